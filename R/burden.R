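# Risk-residue accumulation: best-guess genotype calls, count-bin odds
# ratios, linearity of OR versus count, additive-versus-interaction model
# comparison by AIC, and weighted/unweighted genetic risk score ROC
# comparison.

#' Best-guess genotype calls from dosages
#'
#' Rounds each dosage to the nearest genotype and masks calls whose implied
#' genotype probability (approximated as 1 minus the distance to the
#' nearest integer) falls below \code{certainty_min}.
#'
#' @param dosages Numeric matrix (individuals x markers) of dosages.
#' @param certainty_min Certainty floor in (0.5, 1], default 0.8.
#' @return Integer matrix with NA for uncertain calls.
#' @export
hard_call <- function(dosages, certainty_min = 0.8) {
  stopifnot(certainty_min > 0.5, certainty_min <= 1)
  g <- round(dosages)
  unc <- (1 - abs(dosages - g)) < certainty_min
  g[unc] <- NA
  storage.mode(g) <- "integer"
  g
}

#' Risk-residue burden analysis
#'
#' From hard-called genotypes at the independent risk residues: per-count
#' odds ratios versus the zero-count reference (2x2 contingency, Woolf
#' confidence intervals), a least-squares line of OR on count, additive
#' versus all-pairwise-interaction logistic models compared by AIC, and
#' weighted (sum of count x log OR) versus unweighted genetic risk scores
#' compared by ROC AUC with a paired bootstrap test. Individuals with any
#' missing call are excluded.
#'
#' @param calls Integer matrix (individuals x risk residues) of best-guess
#'   genotype counts.
#' @param panel An \code{hla_panel} (same individuals, in order).
#' @param weights Per-residue log odds ratios for the weighted score;
#'   default, estimated from per-residue covariate-free logistic fits.
#' @param top_bin Counts at or above this are pooled into the top bin
#'   (default 9, i.e. ">8" as conventionally reported).
#' @param auc Also compute the ROC comparison (pROC bootstrap, 2000
#'   resamples); default TRUE.
#' @return list of class \code{burden_table}: bins (data.frame), linear_fit
#'   (slope, intercept, r2), aic_additive, aic_interaction, auc_weighted,
#'   auc_unweighted, auc_p, n_excluded.
#' @export
burden_analysis <- function(calls, panel, weights = NULL, top_bin = 9L,
                            auc = TRUE) {
  stopifnot(nrow(calls) == nrow(panel))
  ok <- stats::complete.cases(calls) & !is.na(panel$status)
  n_excluded <- sum(!ok)
  calls <- calls[ok, , drop = FALSE]
  y <- panel$status[ok]
  count <- rowSums(calls)
  binned <- pmin(count, top_bin)
  if (!any(binned == 0)) stop("empty zero-count reference bin")
  bins <- sort(unique(binned))
  n10 <- sum(y == 1 & binned == 0); n00 <- sum(y == 0 & binned == 0)
  bt <- do.call(rbind, lapply(bins, function(b) {
    n1 <- sum(y == 1 & binned == b); n0 <- sum(y == 0 & binned == b)
    if (b == 0) {
      or <- 1; lci <- NA; uci <- NA
    } else if (n1 == 0 || n0 == 0) {
      or <- NA; lci <- NA; uci <- NA
    } else {
      or <- (n1 / n0) / (n10 / n00)
      selog <- sqrt(1 / n1 + 1 / n0 + 1 / n10 + 1 / n00)
      lci <- exp(log(or) - 1.959964 * selog)
      uci <- exp(log(or) + 1.959964 * selog)
    }
    data.frame(count = b, label = ifelse(b == top_bin,
                                         paste0(">", top_bin - 1L), as.character(b)),
               n_cases = n1, n_controls = n0, or = or, lci = lci, uci = uci)
  }))
  # precision-weighted least squares: high-count bins hold few individuals
  # and their OR estimates are noisy, so weight each bin by the inverse
  # delta-method variance of its OR (reference bin gets the variance of an
  # OR of 1 against itself, i.e. the largest weight)
  fitdat <- bt[!is.na(bt$or), ]
  wvar <- vapply(seq_len(nrow(fitdat)), function(i) {
    n1 <- fitdat$n_cases[i]; n0 <- fitdat$n_controls[i]
    fitdat$or[i]^2 * (1 / max(n1, 1) + 1 / max(n0, 1) + 1 / n10 + 1 / n00)
  }, numeric(1))
  w <- 1 / wvar
  lf <- stats::lm(fitdat$or ~ fitdat$count, weights = w)
  wmean <- sum(w * fitdat$or) / sum(w)
  r2w <- 1 - sum(w * stats::residuals(lf)^2) /
    sum(w * (fitdat$or - wmean)^2)
  linear_fit <- list(slope = unname(stats::coef(lf)[2]),
                     intercept = unname(stats::coef(lf)[1]),
                     r2 = r2w)
  # additive vs all-pairwise-interaction logistic models on residue calls
  df <- as.data.frame(calls)
  names(df) <- paste0("r", seq_len(ncol(calls)))
  df$y <- y
  add_form <- stats::as.formula(paste("y ~", paste(names(df)[-ncol(df)],
                                                   collapse = " + ")))
  int_form <- stats::as.formula(paste("y ~ (",
                                      paste(names(df)[-ncol(df)], collapse = " + "),
                                      ")^2"))
  m_add <- stats::glm(add_form, data = df, family = stats::binomial())
  m_int <- suppressWarnings(stats::glm(int_form, data = df,
                                       family = stats::binomial()))
  if (is.null(weights)) {
    weights <- vapply(seq_len(ncol(calls)), function(j) {
      f <- fit_logit(cbind(1, calls[, j]), y)
      f$coef[2]
    }, numeric(1))
  }
  grs_w <- as.numeric(calls %*% weights)
  grs_u <- count
  out <- list(bins = bt, linear_fit = linear_fit,
              aic_additive = stats::AIC(m_add),
              aic_interaction = stats::AIC(m_int),
              auc_weighted = NA_real_, auc_unweighted = NA_real_,
              auc_p = NA_real_, n_excluded = n_excluded)
  if (auc) {
    r_w <- pROC::roc(y, grs_w, quiet = TRUE, direction = "<")
    r_u <- pROC::roc(y, grs_u, quiet = TRUE, direction = "<")
    out$auc_weighted <- as.numeric(pROC::auc(r_w))
    out$auc_unweighted <- as.numeric(pROC::auc(r_u))
    cmp <- pROC::roc.test(r_w, r_u, method = "bootstrap", boot.n = 2000,
                          paired = TRUE)
    out$auc_p <- cmp$p.value
  }
  class(out) <- "burden_table"
  out
}

#' @export
print.burden_table <- function(x, ...) {
  cat("<burden_table>\n")
  print(x$bins, row.names = FALSE)
  cat(sprintf("OR ~ count: slope %.3f, R2 %.3f | AIC additive %.1f vs interaction %.1f\n",
              x$linear_fit$slope, x$linear_fit$r2,
              x$aic_additive, x$aic_interaction))
  if (!is.na(x$auc_weighted))
    cat(sprintf("AUC weighted %.3f vs unweighted %.3f (p = %.3g)\n",
                x$auc_weighted, x$auc_unweighted, x$auc_p))
  invisible(x)
}
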