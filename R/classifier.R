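# Threshold-and-intersection logic turning differential results into
# damage-responsive, maturity-silenced and DRMS peak sets.

#' Call a peak set from a differential result
#'
#' Applies strict thresholds: a peak is called when `padj < padj_cut` and
#' `log2fc > lfc_cut` (direction `"up"`) or `log2fc < -lfc_cut`
#' (direction `"down"`). Peaks with missing `padj` (excluded from testing)
#' are not callable and are skipped.
#'
#' @param diff a `diff_result` data.frame from [nb_wald_test()].
#' @param direction `"up"` (more accessible in the contrast numerator) or
#'   `"down"`.
#' @param padj_cut adjusted p-value threshold in (0, 1].
#' @param lfc_cut absolute log2 fold-change threshold (>= 0).
#' @return character vector of called `peak_id`s.
#' @export
call_set <- function(diff, direction = c("up", "down"), padj_cut = 0.1,
                     lfc_cut = 0.5) {
  direction <- match.arg(direction)
  if (!(padj_cut > 0 && padj_cut <= 1)) stop("padj_cut must be in (0, 1]")
  if (lfc_cut < 0) stop("lfc_cut must be >= 0")
  if (!nrow(diff)) return(character())
  ok <- !is.na(diff$padj) & !is.na(diff$log2fc)
  hit <- ok & diff$padj < padj_cut &
    if (direction == "up") diff$log2fc > lfc_cut else diff$log2fc < -lfc_cut
  diff$peak_id[hit]
}

#' Combine calls into a DRMS call set
#'
#' Intersects the three primary calls: `drms = dr_early & ms` (peaks that
#' open on damage in early-stage tissue and lose accessibility in damaged
#' late-stage tissue) and `dr_both = dr_early & dr_late`. Set-algebra
#' invariants (`drms` contained in both parents, etc.) are asserted after
#' construction.
#'
#' @param dr_early,dr_late,ms character vectors of peak ids: up-called
#'   damaged-vs-undamaged at early and late stage, and down-called
#'   late-damaged vs early-damaged (maturity silencing; late stage is the
#'   contrast numerator).
#' @param thresholds named list or vector recording the cutoffs used
#'   (stored as metadata).
#' @return object of class `drms_callset`: list with the five sets and a
#'   `summary` data.frame of set sizes plus the DRMS fraction of the
#'   early damage-responsive set.
#' @export
classify_drms <- function(dr_early, dr_late, ms, thresholds = NULL) {
  dr_early <- sort(unique(as.character(dr_early)))
  dr_late <- sort(unique(as.character(dr_late)))
  ms <- sort(unique(as.character(ms)))
  dr_both <- intersect(dr_early, dr_late)
  drms <- intersect(dr_early, ms)
  stopifnot(all(drms %in% dr_early), all(drms %in% ms),
            setequal(dr_both, intersect(dr_early, dr_late)))
  summary <- data.frame(
    set = c("dr_early", "dr_late", "dr_both", "ms", "drms"),
    n = c(length(dr_early), length(dr_late), length(dr_both), length(ms),
          length(drms)),
    stringsAsFactors = FALSE
  )
  out <- list(dr_early = dr_early, dr_late = dr_late, dr_both = dr_both,
              ms = ms, drms = drms, summary = summary,
              drms_fraction_of_dr_early =
                if (length(dr_early)) length(drms) / length(dr_early)
                else NA_real_,
              thresholds = thresholds)
  class(out) <- "drms_callset"
  out
}

#' @export
print.drms_callset <- function(x, ...) {
  cat("DRMS call set\n")
  print(x$summary, row.names = FALSE)
  if (!is.na(x$drms_fraction_of_dr_early)) {
    cat(sprintf("DRMS fraction of early damage-responsive set: %.3f\n",
                x$drms_fraction_of_dr_early))
  }
  invisible(x)
}

#' Write a call set to disk
#'
#' Writes a per-peak membership table (TSV, one row per peak appearing in
#' any set, sorted by peak id) and a JSON summary of set sizes, thresholds
#' and the DRMS fraction. The pair round-trips through
#' [read_callset()] losslessly.
#'
#' @param callset a `drms_callset`.
#' @param tsv_path,json_path output paths.
#' @return invisibly, the membership data.frame.
#' @export
write_callset <- function(callset, tsv_path, json_path) {
  sets <- c("dr_early", "dr_late", "dr_both", "ms", "drms")
  ids <- sort(unique(unlist(callset[sets])))
  member <- data.frame(peak_id = ids, stringsAsFactors = FALSE)
  for (s in sets) member[[s]] <- ids %in% callset[[s]]
  write.table(member, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(counts = setNames(as.list(callset$summary$n), callset$summary$set),
         drms_fraction_of_dr_early = callset$drms_fraction_of_dr_early,
         thresholds = callset$thresholds),
    json_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(member)
}

#' Read a call set written by [write_callset()]
#'
#' @param tsv_path membership TSV path.
#' @return a `drms_callset` reconstructed from the membership table.
#' @export
read_callset <- function(tsv_path) {
  member <- read.delim(tsv_path, stringsAsFactors = FALSE)
  classify_drms(dr_early = member$peak_id[member$dr_early],
                dr_late = member$peak_id[member$dr_late],
                ms = member$peak_id[member$ms])
}
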