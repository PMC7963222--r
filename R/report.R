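#' Per-lesion white-matter-like percentage report
#'
#' Collects per-lesion classification results into the table layout of the
#' study design: one row per lesion with voxel count and WM% per contrast,
#' followed by per-type mean (SD) aggregate rows recomputed from the lesion
#' rows.  Percentages are kept at full precision in `lesions` and rounded to
#' integers only in the formatted table.
#'
#' @param results data frame with columns `lesion_id`, `type`, `n_voxels`,
#'   `contrast`, `wm_percent` (one row per lesion x contrast).
#' @return object of class `lesion_report`: `lesions` (wide data frame),
#'   `summary` (per-type `mean_<contrast>` / `sd_<contrast>`), `contrasts`.
#' @export
lesion_report <- function(results) {
  results <- as.data.frame(results)
  need <- c("lesion_id", "type", "n_voxels", "contrast", "wm_percent")
  stopifnot(all(need %in% names(results)), nrow(results) >= 1L)
  contrasts <- unique(results$contrast)
  ids <- unique(results$lesion_id)
  wide <- data.frame(lesion_id = ids,
                     type = results$type[match(ids, results$lesion_id)],
                     n_voxels = results$n_voxels[match(ids,
                                                       results$lesion_id)],
                     stringsAsFactors = FALSE)
  for (ct in contrasts) {
    sub <- results[results$contrast == ct, ]
    wide[[ct]] <- sub$wm_percent[match(ids, sub$lesion_id)]
  }
  types <- unique(wide$type)
  summ <- data.frame(type = types, n_lesions = NA_integer_,
                     stringsAsFactors = FALSE)
  for (ct in contrasts) {
    summ[[paste0("mean_", ct)]] <- NA_real_
    summ[[paste0("sd_", ct)]] <- NA_real_
  }
  for (i in seq_along(types)) {
    rows <- wide[wide$type == types[i], ]
    summ$n_lesions[i] <- nrow(rows)
    for (ct in contrasts) {
      summ[[paste0("mean_", ct)]][i] <- mean(rows[[ct]])
      summ[[paste0("sd_", ct)]][i] <-
        if (nrow(rows) > 1L) stats::sd(rows[[ct]]) else 0
    }
  }
  structure(list(lesions = wide, summary = summ, contrasts = contrasts),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat("Percentages of lesion voxels classified as white-matter-like\n")
  tab <- x$lesions
  for (ct in x$contrasts) tab[[ct]] <- round(tab[[ct]])
  print(tab, row.names = FALSE)
  cat("\nPer-type mean (SD):\n")
  s <- x$summary
  out <- data.frame(type = s$type, n = s$n_lesions)
  for (ct in x$contrasts)
    out[[ct]] <- sprintf("%d (%d)", round(s[[paste0("mean_", ct)]]),
                         round(s[[paste0("sd_", ct)]]))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Write a lesion report as tab-separated values
#'
#' Two TSV blocks: the per-lesion table and the per-type aggregates
#' (full-precision values; round for display).
#'
#' @param report a `lesion_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "lesion_report"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report$lesions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("", con)
  utils::write.table(report$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
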