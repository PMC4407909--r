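# qPCR fold-enrichment: enrichment success is estimated from the crossing
# point (Cp) difference between enriched and unenriched aliquots of a
# library, fold = efficiency^|mean(enriched Cp) - mean(unenriched Cp)| with
# an assumed amplification efficiency of 1.78 per cycle.

#' Fold enrichment from paired Cp records
#'
#' @param enriched,unenriched one-row data.frames or lists with fields
#'   `library`, `amplicon`, `blocker` and `cp` (numeric vector of replicate
#'   crossing points). Library and amplicon must agree between the two.
#' @param efficiency assumed per-cycle amplification efficiency, default 1.78.
#' @return one-row data.frame: `library`, `amplicon`, `blocker`, `delta_cp`
#'   (mean enriched minus mean unenriched), `fold`.
#' @export
fold_enrichment <- function(enriched, unenriched, efficiency = 1.78) {
  if (!identical(enriched$library, unenriched$library) ||
      !identical(enriched$amplicon, unenriched$amplicon)) {
    stop("enriched and unenriched records must share library and amplicon")
  }
  stopifnot(length(enriched$cp) >= 1, length(unenriched$cp) >= 1,
            all(enriched$cp > 0), all(unenriched$cp > 0), efficiency > 0)
  delta <- mean(enriched$cp) - mean(unenriched$cp)
  data.frame(library = enriched$library, amplicon = enriched$amplicon,
             blocker = enriched$blocker %||% NA_character_,
             delta_cp = delta, fold = efficiency^abs(delta),
             stringsAsFactors = FALSE)
}

#' Read a Cp table and compute all fold enrichments
#'
#' The CSV has columns `library`, `amplicon`, `treatment`
#' (`enriched`/`unenriched`), `blocker`, and replicate columns `rep1..repK`.
#' Replicates are aggregated by arithmetic mean; each (library, amplicon,
#' blocker) pair of treatments yields one fold-enrichment row.
#'
#' @param path CSV path, or a data.frame in the same layout.
#' @param efficiency assumed amplification efficiency, default 1.78.
#' @return data.frame of [fold_enrichment()] rows.
#' @export
enrichment_folds <- function(path, efficiency = 1.78) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  repcols <- grep("^rep\\d+$", names(df), value = TRUE)
  stopifnot(length(repcols) >= 1,
            all(c("library", "amplicon", "treatment", "blocker") %in% names(df)))
  keys <- unique(df[, c("library", "amplicon", "blocker")])
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    sel <- df$library == keys$library[i] & df$amplicon == keys$amplicon[i] &
      df$blocker == keys$blocker[i]
    rec <- function(treat) {
      r <- df[sel & df$treatment == treat, , drop = FALSE]
      if (nrow(r) != 1) {
        stop("expected one ", treat, " record for (",
             keys$library[i], ", ", keys$amplicon[i], ")")
      }
      list(library = r$library, amplicon = r$amplicon, blocker = r$blocker,
           cp = unlist(r[repcols], use.names = FALSE))
    }
    out <- rbind(out, fold_enrichment(rec("enriched"), rec("unenriched"),
                                      efficiency = efficiency))
  }
  out
}

#' Summarize fold enrichments by pool / blocker / amplicon
#'
#' Arithmetic mean of fold values within each group (averaging over folds,
#' not over delta-Cp; set `on = "delta_cp"` for the per-cycle alternative,
#' reported back on the fold scale).
#'
#' @param results data.frame from [enrichment_folds()].
#' @param group_by character vector of grouping columns, default `"blocker"`.
#' @param on `"fold"` (default) or `"delta_cp"`.
#' @param efficiency used only when `on = "delta_cp"`.
#' @return data.frame of group means with an `n` column.
#' @export
summarize_pools <- function(results, group_by = "blocker", on = c("fold", "delta_cp"),
                            efficiency = 1.78) {
  on <- match.arg(on)
  stopifnot(all(group_by %in% names(results)), nrow(results) >= 1)
  key <- interaction(results[group_by], drop = TRUE)
  groups <- split(results, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    mf <- if (on == "fold") mean(g$fold) else efficiency^mean(abs(g$delta_cp))
    cbind(g[1, group_by, drop = FALSE],
          data.frame(mean_fold = mf, n = nrow(g)))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[group_by]), , drop = FALSE]
}
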