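# Generics and accessor methods for the S4 containers.

#' @rdname SdAbSet-class
#' @param x an `SdAbSet`.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname SdAbSet-class
#' @export
setMethod("records", "SdAbSet", function(x) x@records)

#' @rdname SdAbSet-class
#' @export
setGeneric("funnel", function(x) standardGeneric("funnel"))

#' @rdname SdAbSet-class
#' @export
setMethod("funnel", "SdAbSet", function(x) x@funnel)

#' @rdname SdAbSet-class
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))

#' @rdname SdAbSet-class
#' @export
setMethod("verdicts", "SdAbSet", function(x) x@verdicts)

#' @rdname SdAbSet-class
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname SdAbSet-class
#' @export
setMethod("nRecords", "SdAbSet", function(x) nrow(x@records))

#' Full sequences of a curated set as an AAStringSet
#'
#' @param x an [SdAbSet-class]; records without a full sequence are dropped.
#' @return A [Biostrings::AAStringSet] named by record identifier.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname sequences
#' @export
setMethod("sequences", "SdAbSet", function(x) {
  rec <- x@records
  keep <- isPresent(rec$full_sequence)
  Biostrings::AAStringSet(structure(rec$full_sequence[keep],
                                    names = rec$record_id[keep]))
})

# Internal: replace the record table while appending funnel rows.
replaceRecords <- function(set, records, step = NULL, removed = NULL,
                           new_verdicts = NULL) {
  fn <- set@funnel
  if (!is.null(step))
    fn <- rbind(fn, funnelRow(step, nrow(set@records), removed))
  vd <- set@verdicts
  if (!is.null(new_verdicts) && nrow(new_verdicts) > 0L)
    vd <- rbind(vd, new_verdicts)
  rownames(records) <- NULL
  new("SdAbSet", records = records, funnel = fn, verdicts = vd,
      sourceCounts = set@sourceCounts)
}
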