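#' Repeated-measures / mixed ANOVA on a measure table
#'
#' Classical sums-of-squares decomposition with subject as a random blocking
#' factor: each within-subject effect is tested against its
#' subject-by-effect interaction; a between-subjects factor is tested
#' against subjects-within-groups. With all-two-level factors every
#' numerator df is 1 and no sphericity correction is needed. The engine is
#' `stats::aov` with an `Error(subject/...)` stratum structure; this wrapper
#' validates balance (unbalanced within-cells raise an error listing the
#' missing cells) and extracts a tidy effect table.
#'
#' @param table long-format measure table for one measure: columns
#'   `subject`, `value`, the within factors, and optionally a between
#'   factor (constant within subject).
#' @param within character vector of within-subject factor names.
#' @param between optional between-subjects factor name.
#' @param dv name of the value column.
#' @return an `anova_result` data.frame: `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova <- function(table, within, between = NULL, dv = "value") {
  stopifnot(all(c("subject", dv, within, between) %in% names(table)))
  tab <- table
  tab$.value <- tab[[dv]]
  # balance check: every subject must carry the full within-cell crossing once
  cells <- interaction(tab[within], drop = FALSE, sep = ":")
  ct <- table(tab$subject, cells)
  if (any(ct != 1)) {
    bad <- which(ct != 1, arr.ind = TRUE)
    desc <- apply(bad, 1, function(ij)
      sprintf("%s x %s (n=%d)", rownames(ct)[ij[1]], colnames(ct)[ij[2]],
              ct[ij[1], ij[2]]))
    stopf("unbalanced within-subject cells:\n  %s",
          paste(utils::head(desc, 10), collapse = "\n  "))
  }
  if (!is.null(between)) {
    g <- tapply(as.character(tab[[between]]), tab$subject,
                function(v) length(unique(v)))
    if (any(g != 1)) stopf("between factor varies within subject")
  }
  for (f in c("subject", within, between)) tab[[f]] <- factor(tab[[f]])

  wterm <- paste(within, collapse = "*")
  fixed <- if (is.null(between)) wterm else paste(between, wterm, sep = "*")
  form <- stats::as.formula(sprintf(".value ~ %s + Error(subject/(%s))",
                                    fixed, wterm))
  fit <- stats::aov(form, data = tab)
  out <- list()
  ss_all <- 0
  for (stratum in summary(fit)) {
    smry <- if (is.list(stratum)) stratum[[1]] else stratum
    df <- as.data.frame(smry)
    effects <- trimws(rownames(df))
    ss_all <- ss_all + sum(df$`Sum Sq`, na.rm = TRUE)
    res_i <- which(effects == "Residuals")
    if (!length(res_i)) next
    df2 <- df$Df[res_i]
    for (i in seq_len(nrow(df))) {
      if (i == res_i || is.na(df$`F value`[i])) next
      out[[length(out) + 1]] <- data.frame(
        effect = effects[i], df1 = df$Df[i], df2 = df2,
        F = df$`F value`[i], p = df$`Pr(>F)`[i],
        ss = df$`Sum Sq`[i], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # conservation bookkeeping: all effect + residual + subject SS
  attr(res, "total_ss") <- ss_all
  attr(res, "grand_ss") <- sum((tab$.value - mean(tab$.value))^2)
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Simple-effects analyses within levels of a between factor
#'
#' Re-runs [rm_anova()] on the within-subject factors separately inside each
#' level of the splitting factor.
#'
#' @param table long-format measure table (see [rm_anova()]).
#' @param split_by factor name to split on.
#' @param within within-subject factor names.
#' @param dv value column name.
#' @return named list of `anova_result`s, one per level.
#' @export
simple_effects <- function(table, split_by, within, dv = "value") {
  stopifnot(split_by %in% names(table))
  lv <- unique(as.character(table[[split_by]]))
  out <- lapply(lv, function(l)
    rm_anova(table[table[[split_by]] == l, , drop = FALSE], within = within,
             dv = dv))
  stats::setNames(out, lv)
}

# Convenience accessor: one effect row from an anova_result.
anova_effect <- function(res, effect) {
  i <- match(effect, res$effect)
  if (is.na(i)) stopf("effect '%s' not in result (%s)", effect,
                      paste(res$effect, collapse = ", "))
  res[i, ]
}
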