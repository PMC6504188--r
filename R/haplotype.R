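# EM haplotype-frequency estimation from unphased multi-locus genotypes,
# haplotype association via posterior expected dosages, and pairwise
# linkage disequilibrium (Lewontin D', r^2).

#' Genotype strings from best-guess biallelic calls
#'
#' Encodes 0/1/2 presence counts as unordered genotype pairs over the
#' alleles \code{"1"} (presence) and \code{"0"} (absence), the input form
#' of \code{\link{em_haplotypes}}.
#'
#' @param calls Integer matrix (individuals x loci).
#' @return Character matrix of \code{"a/b"} genotypes.
#' @export
genotype_from_calls <- function(calls) {
  g <- matrix(NA_character_, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  g[calls == 0L] <- "0/0"
  g[calls == 1L] <- "0/1"
  g[calls == 2L] <- "1/1"
  g
}

# Enumerate the compatible ordered-up-to-swap haplotype pairs of one
# individual; returns a 2-column matrix of haplotype strings.
enumerate_pairs <- function(geno_row) {
  alleles <- strsplit(geno_row, "/", fixed = TRUE)
  het <- vapply(alleles, function(a) a[1] != a[2], logical(1))
  nhet <- sum(het)
  if (nhet <= 1L) {
    h1 <- vapply(alleles, `[`, "", 1)
    h2 <- vapply(alleles, `[`, "", 2)
    return(matrix(c(paste(h1, collapse = "|"), paste(h2, collapse = "|")),
                  1, 2))
  }
  free <- which(het)[-1]                      # first het locus anchors phase
  combos <- expand.grid(rep(list(c(1L, 2L)), length(free)))
  out <- matrix(NA_character_, nrow(combos), 2)
  for (r in seq_len(nrow(combos))) {
    pick <- rep(1L, length(geno_row))
    pick[free] <- as.integer(combos[r, ])
    h1 <- mapply(function(a, p) a[p], alleles, pick)
    h2 <- mapply(function(a, p) a[3L - p], alleles, pick)
    out[r, ] <- c(paste(h1, collapse = "|"), paste(h2, collapse = "|"))
  }
  out
}

#' EM haplotype-frequency estimation
#'
#' Maximum-likelihood haplotype frequencies over phase ambiguity by
#' expectation-maximization, with seeded random restarts (best likelihood
#' kept) and a monotone-likelihood check every iteration.
#'
#' @param geno Character matrix (individuals x loci) of \code{"a/b"}
#'   genotype strings; alleles are arbitrary labels, so multi-allelic loci
#'   are supported. Individuals with any missing locus are dropped.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap per restart (default 1000).
#' @param n_restarts Random restarts (default 5; the first is uniform).
#' @param seed Seed for the restart draws.
#' @param max_configs Cap on the summed phase-configuration count.
#' @return list of class \code{haplotype_table}: \code{haplotypes}
#'   (data.frame haplotype/freq), \code{loglik}, \code{iterations},
#'   \code{dosage} (individuals x haplotypes posterior expected counts),
#'   \code{individuals} (kept row indices), \code{n_dropped}.
#' @export
em_haplotypes <- function(geno, tol = 1e-8, max_iter = 1000L,
                          n_restarts = 5L, seed = 1L, max_configs = 1e6) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) >= 2L)
  ok <- stats::complete.cases(geno)
  if (!any(ok)) stop("all individuals have missing genotypes")
  kept <- which(ok)
  # individuals sharing a multi-locus genotype share the same configuration
  # set, so enumerate and weight by distinct pattern
  pattern <- apply(geno[kept, , drop = FALSE], 1, paste, collapse = " ")
  upat <- unique(pattern)
  pat_of <- match(pattern, upat)
  pat_n <- tabulate(pat_of, length(upat))
  pairs <- lapply(strsplit(upat, " ", fixed = TRUE), enumerate_pairs)
  if (sum(vapply(pairs, nrow, 0L)) > max_configs)
    stop("phase-configuration space exceeds cap (", max_configs, ")")
  haps <- sort(unique(unlist(pairs)))
  H <- length(haps)
  idx <- lapply(pairs, function(pm)
    cbind(match(pm[, 1], haps), match(pm[, 2], haps)))
  n <- length(kept)
  post <- function(f, ij) {
    w <- f[ij[, 1]] * f[ij[, 2]] * ifelse(ij[, 1] == ij[, 2], 1, 2)
    sw <- sum(w)
    if (sw <= 0) list(w = rep(1 / nrow(ij), nrow(ij)), sw = NA_real_)
    else list(w = w / sw, sw = sw)
  }
  run_em <- function(f) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      counts <- numeric(H)
      ll <- 0
      for (u in seq_along(idx)) {
        ij <- idx[[u]]
        pw <- post(f, ij)
        if (!is.na(pw$sw)) ll <- ll + pat_n[u] * log(pw$sw)
        inc <- pat_n[u] * pw$w
        counts[ij[, 1]] <- counts[ij[, 1]] + inc
        counts[ij[, 2]] <- counts[ij[, 2]] + inc
      }
      if (ll < ll_old - 1e-8)
        stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
      f <- counts / (2 * n)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
        return(list(f = f, ll = ll, iter = it))
      }
      ll_old <- ll
    }
    list(f = f, ll = ll_old, iter = max_iter)
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    f0 <- if (r == 1L) rep(1 / H, H) else {
      g <- stats::rgamma(H, 1); g / sum(g)
    }
    fit <- run_em(f0)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  f <- best$f
  # posterior expected haplotype counts per pattern, expanded per individual
  pdos <- matrix(0, length(upat), H)
  for (u in seq_along(idx)) {
    ij <- idx[[u]]
    pw <- post(f, ij)
    pdos[u, ij[, 1]] <- pdos[u, ij[, 1]] + pw$w
    # homozygous-pair rows add to the same cell twice on purpose
    pdos[u, ij[, 2]] <- pdos[u, ij[, 2]] + pw$w
  }
  dos <- pdos[pat_of, , drop = FALSE]
  colnames(dos) <- haps
  structure(list(haplotypes = data.frame(haplotype = haps, freq = f,
                                         stringsAsFactors = FALSE),
                 loglik = best$ll, iterations = best$iter, dosage = dos,
                 individuals = kept, n_dropped = sum(!ok)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", nrow(x$haplotypes), " haplotypes, logLik ",
      sprintf("%.3f", x$loglik), " (", x$iterations, " EM iterations)\n",
      sep = "")
  print(utils::head(x$haplotypes[order(-x$haplotypes$freq), ], 10),
        row.names = FALSE)
  invisible(x)
}

#' Haplotype association against case/control status
#'
#' Logistic regression of status on per-haplotype dosage (EM posterior
#' expected counts by default, or best-guess phased counts), corrected by
#' sex and three principal components. Haplotypes below the frequency
#' floor are skipped with a reason.
#'
#' @param ht A \code{haplotype_table}.
#' @param panel An \code{hla_panel} whose rows the genotype matrix rows
#'   index into.
#' @param targets Optional haplotype strings to test (default all).
#' @param min_freq Frequency floor (default 0.005).
#' @param method \code{"posterior"} (default) or \code{"best_guess"}.
#' @param covariates Include sex + PC correction (default TRUE).
#' @return data.frame: haplotype, freq, beta, se, or, lci, uci, p, reason.
#' @export
haplotype_assoc <- function(ht, panel, targets = NULL, min_freq = 0.005,
                            method = c("posterior", "best_guess"),
                            covariates = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(ht, "haplotype_table"))
  p2 <- panel[ht$individuals, , drop = FALSE]
  dos <- ht$dosage
  if (method == "best_guess") dos <- round(dos)
  if (is.null(targets)) targets <- ht$haplotypes$haplotype
  rows <- lapply(targets, function(h) {
    fr <- ht$haplotypes$freq[match(h, ht$haplotypes$haplotype)]
    base <- data.frame(haplotype = h, freq = ifelse(is.na(fr), 0, fr),
                       beta = NA_real_, se = NA_real_, or = NA_real_,
                       lci = NA_real_, uci = NA_real_, p = NA_real_,
                       reason = NA_character_, stringsAsFactors = FALSE)
    if (is.na(fr) || !h %in% colnames(dos)) {
      base$reason <- "absent"
      return(base)
    }
    if (fr < min_freq) {
      base$reason <- "below_frequency_floor"
      return(base)
    }
    r <- fit_biallelic(dos[, h], p2, covariates = covariates)
    base[c("beta", "se", "or", "lci", "uci", "p", "reason")] <-
      r[c("beta", "se", "or", "lci", "uci", "p", "reason")]
    base
  })
  do.call(rbind, rows)
}

#' Lewontin linkage disequilibrium for one allele pair
#'
#' From the haplotype frequency of carrying both alleles and the two
#' marginal allele frequencies: \code{D = f_AB - f_A f_B}; \code{D'}
#' normalizes D by its maximum attainable magnitude given the margins; and
#' \code{r^2 = D^2 / (f_A(1-f_A) f_B(1-f_B))}.
#'
#' @param f_ab Joint haplotype frequency.
#' @param f_a,f_b Marginal allele frequencies.
#' @return list(D, Dprime, r2); NA for a monomorphic locus.
#' @export
ld_pair <- function(f_ab, f_a, f_b) {
  stopifnot(f_ab >= 0, f_ab <= 1, f_a >= 0, f_a <= 1, f_b >= 0, f_b <= 1)
  if (f_a %in% c(0, 1) || f_b %in% c(0, 1))
    return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_))
  D <- f_ab - f_a * f_b
  dmax <- if (D > 0) min(f_a * (1 - f_b), (1 - f_a) * f_b)
          else min(f_a * f_b, (1 - f_a) * (1 - f_b))
  dprime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (f_a * (1 - f_a) * f_b * (1 - f_b))
  list(D = D, Dprime = dprime, r2 = r2)
}

#' Pairwise LD between two loci of a haplotype table
#'
#' Marginalizes the EM haplotype frequencies to one allele of each of two
#' loci and returns the Lewontin statistics.
#'
#' @param ht A \code{haplotype_table}.
#' @param locus_a,locus_b 1-based locus indices within the haplotype
#'   strings.
#' @param allele_a,allele_b Allele labels at each locus.
#' @return list(D, Dprime, r2).
#' @export
ld_from_haplotypes <- function(ht, locus_a, allele_a, locus_b, allele_b) {
  parts <- strsplit(ht$haplotypes$haplotype, "|", fixed = TRUE)
  la <- vapply(parts, `[`, "", locus_a)
  lb <- vapply(parts, `[`, "", locus_b)
  f <- ht$haplotypes$freq
  ld_pair(sum(f[la == allele_a & lb == allele_b]),
          sum(f[la == allele_a]), sum(f[lb == allele_b]))
}
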