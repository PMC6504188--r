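# Marker-level logistic association, multi-allelic omnibus likelihood-ratio
# tests, and the nested conditional scan.
#
# All case/control models share the covariate treatment: sex and the first
# three principal components, plus any conditioning covariates. Collinear
# columns are dropped by pivoted rank reduction with the degrees of freedom
# adjusted accordingly.

panel_covariates <- function(panel) {
  as.matrix(panel[, c("sex", "pc1", "pc2", "pc3")])
}

# Logistic ML fit via iteratively reweighted least squares; X must include
# the intercept column. Returns coefficients, Wald SEs and the exact
# Bernoulli log-likelihood.
fit_logit <- function(X, y, maxit = 100, eps = 1e-9) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = eps, maxit = maxit)))
  mu <- pmin(1 - 1e-12, pmax(1e-12, fit$fitted.values))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  R <- qr.R(fit$qr)
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  se <- rep(NA_real_, ncol(X))
  if (!is.null(cov)) {
    piv <- fit$qr$pivot
    se[piv] <- sqrt(pmax(0, diag(cov)))
  }
  list(coef = fit$coefficients, se = se, loglik = ll,
       converged = fit$converged, rank = fit$rank)
}

# Drop columns of M that are (numerically) linear combinations of the
# columns of base; returns the kept column indices of M.
independent_columns <- function(M, base = NULL, tol = 1e-7) {
  if (is.null(M) || ncol(M) == 0L) return(integer(0))
  R <- if (is.null(base)) M else {
    qb <- qr(base)
    M - qr.fitted(qb, M)
  }
  q <- qr(R, tol = tol)
  sort(q$pivot[seq_len(q$rank)])
}

#' Biallelic logistic association for one marker
#'
#' Maximum-likelihood logistic regression of case/control status on a
#' single dosage column, corrected by sex and three principal components,
#' plus optional conditioning covariates. Markers with fewer than 10
#' carriers in either outcome group, monomorphic markers, and
#' non-converged/separated fits are returned flagged with \code{p = NA} and
#' a machine-readable \code{reason}.
#'
#' @param dosage_col Numeric dosage vector (one per panel row).
#' @param panel An \code{hla_panel}.
#' @param conditioning Optional numeric matrix of conditioning covariates.
#' @param covariates Include sex + PC correction (default TRUE).
#' @return One-row data.frame: beta, se, or, lci, uci, p, n_cases,
#'   n_controls, fa, fu (case/control allele frequencies), reason.
#' @export
fit_biallelic <- function(dosage_col, panel, conditioning = NULL,
                          covariates = TRUE) {
  y <- panel$status
  C <- if (covariates) panel_covariates(panel) else NULL
  keep <- !is.na(y) & !is.na(dosage_col)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  if (!is.null(conditioning)) keep <- keep & stats::complete.cases(conditioning)
  y <- y[keep]; d <- dosage_col[keep]
  res <- data.frame(beta = NA_real_, se = NA_real_, or = NA_real_,
                    lci = NA_real_, uci = NA_real_, p = NA_real_,
                    n_cases = sum(y == 1), n_controls = sum(y == 0),
                    fa = mean(d[y == 1]) / 2, fu = mean(d[y == 0]) / 2,
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (stats::var(d) < 1e-12) {
    res$reason <- "monomorphic"
    return(res)
  }
  carriers <- d >= 0.5
  if (sum(carriers & y == 1) < 10 || sum(carriers & y == 0) < 10) {
    res$reason <- "too_few_carriers"
    return(res)
  }
  X <- cbind(1, d)
  if (!is.null(C)) X <- cbind(X, C[keep, , drop = FALSE])
  if (!is.null(conditioning)) {
    Z <- conditioning[keep, , drop = FALSE]
    ki <- independent_columns(Z, base = X)
    if (length(ki)) X <- cbind(X, Z[, ki, drop = FALSE])
  }
  f <- fit_logit(X, y)
  if (!f$converged || is.na(f$se[2]) || abs(f$coef[2]) > 15 || f$se[2] > 100) {
    res$reason <- if (!f$converged) "non_convergence" else "separation"
    return(res)
  }
  res$beta <- f$coef[2]; res$se <- f$se[2]
  res$or <- exp(res$beta)
  res$lci <- exp(res$beta - 1.959964 * res$se)
  res$uci <- exp(res$beta + 1.959964 * res$se)
  res$p <- 2 * stats::pnorm(-abs(res$beta / res$se))
  res
}

#' Crude allelic odds ratio from carrier frequencies
#'
#' \code{[f1/(1-f1)] / [f0/(1-f0)]}: the odds ratio recoverable from two
#' printed group frequencies.
#'
#' @param f1,f0 Frequencies in the two groups, strictly inside (0, 1).
#' @return The odds ratio.
#' @examples
#' crude_allelic_or(0.159, 0.094)  # ~1.82
#' @export
crude_allelic_or <- function(f1, f0) {
  if (any(f1 <= 0 | f1 >= 1 | f0 <= 0 | f0 >= 1))
    stop("frequencies must be strictly inside (0,1)")
  (f1 / (1 - f1)) / (f0 / (1 - f0))
}

#' Multi-allelic omnibus likelihood-ratio test at one position
#'
#' Compares the base model A0 (status ~ sex + PCs + conditioning) with the
#' expanded model A1 adding all residue dosages at the position except the
#' most frequent (reference) residue, recomputed in the analyzed sample.
#' The statistic D = -2 ln(L_A0 / L_A1) is referred to a chi-square with
#' degrees of freedom equal to the number of linearly independent residue
#' columns added (collinear columns are dropped and df reduced).
#'
#' @param position An \code{aa_position}.
#' @param dm The \code{hla_dosage} holding the residue markers.
#' @param panel An \code{hla_panel}.
#' @param conditioning Optional numeric conditioning matrix.
#' @param freq_min Residues below this carrier frequency in the analyzed
#'   sample are excluded from the expanded model.
#' @param covariates Include sex + PC correction (default TRUE).
#' @return list of class \code{omnibus_model}: gene, aa_pos, D, df, p,
#'   loglik0, loglik1, reference, residues, n, note.
#' @export
omnibus_test <- function(position, dm, panel, conditioning = NULL,
                         freq_min = 0.005, covariates = TRUE) {
  stopifnot(inherits(position, "aa_position"))
  y <- panel$status
  C <- if (covariates) panel_covariates(panel) else NULL
  keep <- !is.na(y)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  if (!is.null(conditioning)) keep <- keep & stats::complete.cases(conditioning)
  y <- y[keep]
  V <- dm$dosage[keep, position$marker_ids, drop = FALSE]
  cf <- colMeans(V >= 0.5)
  V <- V[, cf >= freq_min, drop = FALSE]
  out <- list(gene = position$gene, aa_pos = position$aa_pos,
              D = NA_real_, df = NA_integer_, p = NA_real_,
              loglik0 = NA_real_, loglik1 = NA_real_,
              reference = NA_character_, residues = colnames(V),
              n = length(y), note = NA_character_)
  class(out) <- "omnibus_model"
  if (ncol(V) < 2L) {
    out$note <- "fewer_than_two_residues"
    return(out)
  }
  ref <- order(-colMeans(V), colnames(V))[1]
  out$reference <- colnames(V)[ref]
  V <- V[, -ref, drop = FALSE]
  X0 <- matrix(1, length(y), 1)
  if (!is.null(C)) X0 <- cbind(X0, C[keep, , drop = FALSE])
  if (!is.null(conditioning)) {
    Z <- conditioning[keep, , drop = FALSE]
    ki <- independent_columns(Z, base = X0)
    if (length(ki)) X0 <- cbind(X0, Z[, ki, drop = FALSE])
  }
  kv <- independent_columns(V, base = X0)
  if (length(kv) < ncol(V)) out$note <- "rank_reduced"
  f0 <- fit_logit(X0, y)
  if (length(kv) == 0L) {
    # residues fully explained by the conditioning set
    out$D <- 0; out$df <- 0L; out$p <- 1
    out$loglik0 <- out$loglik1 <- f0$loglik
    return(out)
  }
  f1 <- fit_logit(cbind(X0, V[, kv, drop = FALSE]), y)
  if (!f0$converged || !f1$converged) {
    out$note <- "non_convergence"
    return(out)
  }
  out$loglik0 <- f0$loglik; out$loglik1 <- f1$loglik
  out$df <- f1$rank - f0$rank
  out$D <- max(0, 2 * (f1$loglik - f0$loglik))
  out$p <- if (out$df > 0) stats::pchisq(out$D, out$df, lower.tail = FALSE) else 1
  out
}

#' @export
print.omnibus_model <- function(x, ...) {
  cat(sprintf("<omnibus> %s-%d: D = %.3f, df = %d, p = %.3g (n = %d)\n",
              x$gene, x$aa_pos, x$D, x$df, x$p, x$n))
  invisible(x)
}

#' Full classical-allele conditioning block for a gene
#'
#' All of the gene's 4-digit allele dosage columns minus the most frequent
#' one (the reference); used as the stage-B conditioning covariates.
#'
#' @param gene Gene name.
#' @param dm An \code{hla_dosage}.
#' @return Numeric matrix (individuals x alleles-1).
#' @export
condition_on_gene_alleles <- function(gene, dm) {
  ids <- dm$markers$id[dm$markers$kind == "ALLELE4D" & dm$markers$gene == gene]
  if (length(ids) < 2L)
    stop("gene ", gene, " has fewer than two 4-digit allele markers")
  A <- dm$dosage[, ids, drop = FALSE]
  ref <- order(-colMeans(A), colnames(A))[1]
  A[, -ref, drop = FALSE]
}

#' Stepwise nested conditional omnibus scan
#'
#' Iterates: (1) omnibus-scan every candidate position given the current
#' conditioning set; (2) if the best position passes \code{alpha_omnibus},
#' record it and add its residue dosages (minus reference) as covariates
#' (stage A); re-scan within the same gene so a second independent position
#' of that gene can enter; then add the gene's full 4-digit allele block
#' (stage B) before the next gene-level iteration. Stops when no position
#' passes. Ties at a step are broken by smaller p, then gene name, then
#' position.
#'
#' @param dm An \code{hla_dosage} (already quality-filtered).
#' @param panel An \code{hla_panel}.
#' @param alpha_omnibus Significance threshold for every omnibus test
#'   (default 5e-5).
#' @param freq_min Carrier-frequency floor for residues inside positions.
#' @param max_steps Safety cap on gene-level iterations.
#' @return list with \code{selected} (data.frame: order, gene, aa_pos, p,
#'   stage) and \code{ledger} (per-scan p-values: step, stage, gene,
#'   aa_pos, D, df, p).
#' @export
stepwise_scan <- function(dm, panel, alpha_omnibus = 5e-5, freq_min = 0.005,
                          max_steps = 10L) {
  positions <- group_positions(dm)
  if (!length(positions))
    return(list(selected = data.frame(), ledger = data.frame()))
  keys <- names(positions)
  cond <- NULL
  selected <- list()
  ledger <- list()
  taken <- character(0)
  step <- 0L
  scan_once <- function(cands, stage_lab) {
    rows <- lapply(cands, function(k) {
      om <- omnibus_test(positions[[k]], dm, panel, conditioning = cond,
                        freq_min = freq_min)
      data.frame(step = step, stage = stage_lab, gene = om$gene,
                 aa_pos = om$aa_pos, D = om$D, df = om$df, p = om$p,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  add_residues <- function(k) {
    pos <- positions[[k]]
    V <- dm$dosage[, pos$marker_ids, drop = FALSE]
    ref <- which(colnames(V) == pos$reference)
    cond <<- cbind(cond, V[, -ref, drop = FALSE])
  }
  while (step < max_steps) {
    step <- step + 1L
    cands <- setdiff(keys, taken)
    if (!length(cands)) break
    sc <- scan_once(cands, "scan")
    ledger[[length(ledger) + 1L]] <- sc
    sc <- sc[!is.na(sc$p), ]
    sc <- sc[order(sc$p, sc$gene, sc$aa_pos), ]
    if (!nrow(sc) || sc$p[1] >= alpha_omnibus) break
    hit_gene <- sc$gene[1]
    k <- keys[vapply(positions, function(p)
      p$gene == hit_gene && p$aa_pos == sc$aa_pos[1], logical(1))]
    selected[[length(selected) + 1L]] <-
      data.frame(order = length(selected) + 1L, gene = sc$gene[1],
                 aa_pos = sc$aa_pos[1], p = sc$p[1], stage = "A",
                 stringsAsFactors = FALSE)
    taken <- c(taken, k)
    add_residues(k)
    # within-gene re-scan before stage B allele conditioning
    repeat {
      wg <- setdiff(keys[vapply(positions, function(p) p$gene == hit_gene,
                                logical(1))], taken)
      if (!length(wg)) break
      sc2 <- scan_once(wg, "within_gene")
      ledger[[length(ledger) + 1L]] <- sc2
      sc2 <- sc2[!is.na(sc2$p), ]
      sc2 <- sc2[order(sc2$p, sc2$gene, sc2$aa_pos), ]
      if (!nrow(sc2) || sc2$p[1] >= alpha_omnibus) break
      k2 <- keys[vapply(positions, function(p)
        p$gene == hit_gene && p$aa_pos == sc2$aa_pos[1], logical(1))]
      selected[[length(selected) + 1L]] <-
        data.frame(order = length(selected) + 1L, gene = sc2$gene[1],
                   aa_pos = sc2$aa_pos[1], p = sc2$p[1], stage = "A",
                   stringsAsFactors = FALSE)
      taken <- c(taken, k2)
      add_residues(k2)
    }
    # stage B: full allele block of the gene
    blk <- tryCatch(condition_on_gene_alleles(hit_gene, dm),
                    error = function(e) NULL)
    if (!is.null(blk)) cond <- cbind(cond, blk)
  }
  list(selected = if (length(selected)) do.call(rbind, selected)
                  else data.frame(),
       ledger = if (length(ledger)) do.call(rbind, ledger)
                else data.frame())
}

#' Autoantibody sub-phenotype contrasts
#'
#' Runs the marker-level and omnibus machinery for the three standard
#' contrasts of one antibody: antibody-positive versus antibody-negative
#' cases (case-only), positive cases versus controls, and negative cases
#' versus controls, with identical covariate treatment throughout.
#'
#' @param dm An \code{hla_dosage}.
#' @param panel An \code{hla_panel} with the antibody column filled for
#'   (some) cases.
#' @param antibody Antibody column name.
#' @param min_stratum Refuse to run when either case stratum is smaller
#'   than this (default 50).
#' @param markers Also run per-marker biallelic fits (default TRUE).
#' @return Named list (\code{case_only}, \code{pos_vs_control},
#'   \code{neg_vs_control}); each element has \code{omnibus} (data.frame)
#'   and optionally \code{markers}.
#' @export
subphenotype_contrasts <- function(dm, panel, antibody, min_stratum = 50L,
                                   markers = TRUE) {
  if (!antibody %in% names(panel)) stop("no antibody column '", antibody, "'")
  ab <- panel[[antibody]]
  pos_cases <- which(panel$status == 1 & !is.na(ab) & ab == 1)
  neg_cases <- which(panel$status == 1 & !is.na(ab) & ab == 0)
  controls <- which(panel$status == 0)
  if (length(pos_cases) < min_stratum || length(neg_cases) < min_stratum)
    stop("antibody stratum too small (", length(pos_cases), " positive / ",
         length(neg_cases), " negative; need >= ", min_stratum, ")")
  run <- function(rows, status) {
    p2 <- panel[rows, , drop = FALSE]
    p2$status <- status
    d2 <- dm
    d2$dosage <- dm$dosage[rows, , drop = FALSE]
    d2$individuals <- rownames(d2$dosage)
    positions <- group_positions(d2)
    om <- do.call(rbind, lapply(positions, function(pos) {
      o <- omnibus_test(pos, d2, p2)
      data.frame(gene = o$gene, aa_pos = o$aa_pos, D = o$D, df = o$df,
                 p = o$p, stringsAsFactors = FALSE)
    }))
    out <- list(omnibus = om)
    if (markers) {
      mk <- do.call(rbind, lapply(seq_len(ncol(d2$dosage)), function(j) {
        r <- fit_biallelic(d2$dosage[, j], p2)
        r$marker <- colnames(d2$dosage)[j]
        r
      }))
      out$markers <- mk[, c("marker", setdiff(names(mk), "marker"))]
    }
    out
  }
  list(
    case_only = run(c(pos_cases, neg_cases),
                    c(rep(1L, length(pos_cases)), rep(0L, length(neg_cases)))),
    pos_vs_control = run(c(pos_cases, controls),
                         c(rep(1L, length(pos_cases)), rep(0L, length(controls)))),
    neg_vs_control = run(c(neg_cases, controls),
                         c(rep(1L, length(neg_cases)), rep(0L, length(controls)))))
}

#' Linear-model conditioning for a continuous outcome
#'
#' Ordinary least-squares analogue of the marker-level machinery for
#' expression-style outcomes, with the same conditioning semantics and the
#' stricter imputation-quality filter used for quantitative analyses.
#'
#' @param outcome Numeric vector (e.g. normalized expression).
#' @param dm An \code{hla_dosage}.
#' @param conditioning Optional numeric conditioning matrix.
#' @param r2_min Imputation-quality floor for this mode (default 0.8,
#'   strict).
#' @return data.frame: marker, beta, se, t, p, r2_model.
#' @export
linear_conditioning <- function(outcome, dm, conditioning = NULL,
                                r2_min = 0.8) {
  keep_m <- dm$markers$r2 > r2_min
  ids <- dm$markers$id[keep_m]
  rows <- lapply(ids, function(id) {
    d <- dm$dosage[, id]
    ok <- !is.na(outcome) & !is.na(d)
    if (!is.null(conditioning)) ok <- ok & stats::complete.cases(conditioning)
    y <- outcome[ok]; x <- d[ok]
    res <- data.frame(marker = id, beta = NA_real_, se = NA_real_,
                      t = NA_real_, p = NA_real_, r2_model = NA_real_,
                      stringsAsFactors = FALSE)
    if (stats::var(x) < 1e-12) return(res)
    X <- cbind(1, x)
    if (!is.null(conditioning)) {
      Z <- conditioning[ok, , drop = FALSE]
      ki <- independent_columns(Z, base = X)
      if (length(ki)) X <- cbind(X, Z[, ki, drop = FALSE])
    }
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    dfres <- length(y) - f$rank
    if (dfres <= 0) return(res)
    sigma2 <- rss / dfres
    R <- qr.R(f$qr)
    cov <- tryCatch(chol2inv(R) * sigma2, error = function(e) NULL)
    if (is.null(cov)) return(res)
    se <- rep(NA_real_, ncol(X)); se[f$qr$pivot] <- sqrt(pmax(0, diag(cov)))
    res$beta <- f$coefficients[2]; res$se <- se[2]
    res$t <- res$beta / res$se
    res$p <- 2 * stats::pt(-abs(res$t), dfres)
    tss <- sum((y - mean(y))^2)
    res$r2_model <- 1 - rss / tss
    res
  })
  do.call(rbind, rows)
}
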