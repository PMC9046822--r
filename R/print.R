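# Compact print methods for the pipeline's result objects.

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC (", x$mode, " mode): ", nrow(x$markers_removed),
      " marker(s) and ", nrow(x$individuals_removed),
      " individual(s) removed\n", sep = "")
  if (nrow(x$markers_removed)) {
    cat("  marker removals by reason:\n")
    print(table(x$markers_removed$reason))
  }
  invisible(x)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("Masking-based imputation validation\n")
  cat(sprintf("  panel size: %d markers; %d genotypes masked\n",
              x$panel_size, x$n_masked))
  cat(sprintf("  proportion imputed correctly: %.4f\n", x$accuracy_overall))
  if (!is.null(x$gebv_concordance)) {
    cat("  GEBV Spearman concordance (imputed vs original):\n")
    for (tr in names(x$gebv_concordance)) {
      cat(sprintf("    %s: %.4f\n", tr, x$gebv_concordance[[tr]]))
    }
  }
  invisible(x)
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("Genomic vs pedigree-only selection (", nrow(x$per_replicate),
      " paired replicates, selection ", x$selection, ")\n", sep = "")
  cat(sprintf("  mean index gain: genomic %.4f, pedigree %.4f (genetic SD/year)\n",
              x$mean_gain_genomic, x$mean_gain_pedigree))
  cat(sprintf("  gain ratio %.3f (95%% CI %.3f-%.3f), one-sided p = %.3g\n",
              x$gain_ratio, x$gain_ratio_ci[1], x$gain_ratio_ci[2],
              x$p_value_one_sided))
  invisible(x)
}

#' @export
print.gs_sim <- function(x, ...) {
  cat("Simulated breeding program (", x$scheme, " scheme, ",
      x$config$n_year_classes, " year classes)\n", sep = "")
  cat(sprintf("  %d individuals (%d founders), %d markers, %d phenotype records\n",
              nrow(x$pedigree), x$config$n_founders, nrow(x$map),
              if (is.null(x$phenotypes)) 0L else nrow(x$phenotypes)))
  cat(sprintf("  %d stored evaluation table(s); traits: %s\n",
              length(x$bv_history), paste(x$trait_model$traits, collapse = ", ")))
  invisible(x)
}
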