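# Marker-based completeness/contamination screen.  The contract mirrors the
# single-copy marker logic of genome-quality tools: completeness is the
# fraction of expected markers seen at least once, contamination the excess
# copy count.

#' Assess genome quality from single-copy marker genes
#'
#' completeness = 100 * (markers present >= 1 copy) / |marker_set|;
#' contamination = 100 * sum(max(0, copies - 1)) / |marker_set|.
#'
#' @param record a [strain_record()].
#' @param marker_set character vector of expected marker labels.  Defaults to
#'   the strain's `qcm*` labels union is not useful for a failing genome, so
#'   pass the dataset-wide marker set (see [qc_marker_set()]).
#' @param thresholds a [default_thresholds()] list.
#' @return one-row data.frame: strain_id, completeness, contamination,
#'   passed.
#' @export
assess_quality <- function(record, marker_set,
                           thresholds = default_thresholds()) {
  if (missing(marker_set) || length(marker_set) == 0L) {
    stop("marker_set must be nonempty")
  }
  copies <- table(record$genes$marker_label)
  present <- vapply(marker_set, function(m) {
    if (m %in% names(copies)) as.integer(copies[[m]]) else 0L
  }, integer(1))
  completeness <- 100 * sum(present >= 1L) / length(marker_set)
  contamination <- 100 * sum(pmax(0L, present - 1L)) / length(marker_set)
  data.frame(strain_id = record$strain_id, completeness = completeness,
             contamination = contamination,
             passed = completeness >= thresholds$completeness_min &
               contamination <= thresholds$contamination_max,
             stringsAsFactors = FALSE)
}

#' Dataset-wide QC marker set
#'
#' All `qcm*` marker labels observed across the dataset.
#' @param records named list of strain records.
#' @export
qc_marker_set <- function(records) {
  labs <- unlist(lapply(records, function(r) r$genes$marker_label),
                 use.names = FALSE)
  sort(unique(labs[startsWith(labs, "qcm")]))
}

#' Filter a dataset on genome quality
#'
#' @param records named list of strain records.
#' @param thresholds a [default_thresholds()] list.
#' @param marker_set expected marker labels; defaults to the dataset's qcm
#'   markers.
#' @return list with `kept` (records), `excluded` (records) and `report`
#'   (per-strain QC table with a `reason` column).
#' @export
filter_dataset <- function(records, thresholds = default_thresholds(),
                           marker_set = qc_marker_set(records)) {
  report <- do.call(rbind, lapply(records, assess_quality,
                                  marker_set = marker_set,
                                  thresholds = thresholds))
  reason <- rep("", nrow(report))
  reason[report$completeness < thresholds$completeness_min] <- "completeness"
  high_cont <- report$contamination > thresholds$contamination_max
  reason[high_cont] <- trimws(paste(reason[high_cont], "contamination"))
  report$reason <- reason
  kept <- records[report$passed]
  excluded <- records[!report$passed]
  if (length(excluded)) {
    message(length(excluded), " genome(s) excluded by QC: ",
            paste(names(excluded), collapse = ", "))
  }
  list(kept = kept, excluded = excluded, report = report)
}
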