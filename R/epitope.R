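# Contact-potential based immunogenic-peptide preference scores for MHC
# binding-groove side-chains, and autoantigen charge/pI profiling with a
# citrullination model (arginine approximated by glutamine).

AA1 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Disease-specific immunogenic residue lists
#'
#' The immunogenic / non-immunogenic peptide residue sets driving the
#' preference score. The RA lists are the experimentally derived
#' over/under-represented immunogenic-peptide residues; for SLE
#' (autoantigens predominantly positively charged) Glu is replaced by Arg
#' in the immunogenic set and Lys is dropped from the non-immunogenic set.
#'
#' @param disease \code{"SLE"} or \code{"RA"}.
#' @return list(immunogenic, non_immunogenic) of one-letter codes.
#' @export
residue_lists <- function(disease = c("SLE", "RA")) {
  disease <- match.arg(disease)
  if (disease == "SLE")
    list(immunogenic = c("W", "F", "I", "R"),
         non_immunogenic = c("S", "M", "Q"))
  else
    list(immunogenic = c("W", "F", "I", "E"),
         non_immunogenic = c("S", "M", "Q", "K"))
}

#' Load a pairwise amino-acid contact potential
#'
#' CSV with one-letter row/column headers; must be a complete, symmetric
#' 20x20 table (lower values = more favorable contact). The packaged
#' default is a synthetic stand-in calibrated to reproduce the published
#' SLE and RA preference-score orderings (see the file header).
#'
#' @param path CSV path; default the packaged matrix.
#' @return 20x20 numeric matrix with one-letter dimnames.
#' @export
load_contact_potential <- function(path = system.file(
    "extdata", "contact_potential_synthetic.csv", package = "hlafinemap")) {
  tab <- utils::read.csv(path, comment.char = "#", row.names = 1,
                         check.names = FALSE)
  M <- as.matrix(tab)
  if (!all(dim(M) == c(20, 20)) || any(is.na(M)))
    stop("contact potential must be a complete 20x20 table")
  if (!setequal(rownames(M), AA1) || !setequal(colnames(M), AA1))
    stop("contact potential must use the 20 one-letter amino-acid codes")
  M <- M[AA1, AA1]
  if (max(abs(M - t(M))) > 1e-9) stop("contact potential must be symmetric")
  M
}

#' Immunogenic-peptide preference scores for all 20 side-chains
#'
#' For each candidate binding-groove side-chain g:
#' \code{score_sum(g) = sum over non-immunogenic a of V(g,a) - sum over
#' immunogenic a of V(g,a)} (and \code{score_min} the same contrast of
#' minima). Since lower potential means more favorable contact, higher
#' scores mark side-chains preferring immunogenic peptide residues --- the
#' predicted risk direction.
#'
#' @param potential 20x20 contact potential matrix.
#' @param lists A \code{\link{residue_lists}} result.
#' @return data.frame (ranked by descending score_sum): aa, score_sum,
#'   score_min, rank.
#' @export
preference_scores <- function(potential, lists) {
  stopifnot(all(c(lists$immunogenic, lists$non_immunogenic) %in% AA1))
  if (length(intersect(lists$immunogenic, lists$non_immunogenic)))
    stop("immunogenic and non-immunogenic lists must be disjoint")
  imm <- lists$immunogenic; non <- lists$non_immunogenic
  zero <- stats::setNames(numeric(20), colnames(potential))
  ssum <- if (length(non)) colSums(potential[non, , drop = FALSE]) else zero
  ssum <- ssum -
    if (length(imm)) colSums(potential[imm, , drop = FALSE]) else zero
  smin <- vapply(AA1, function(g) {
    mn <- if (length(non)) min(potential[non, g]) else 0
    mi <- if (length(imm)) min(potential[imm, g]) else 0
    mn - mi
  }, numeric(1))
  out <- data.frame(aa = AA1, score_sum = as.numeric(ssum[AA1]),
                    score_min = as.numeric(smin[AA1]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score_sum, -out$score_min, out$aa), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify side-chains into risk / intermediate / protective
#'
#' Top \code{n_risk} by score (risk) and bottom \code{n_protective}
#' (protective); the remainder intermediate. Ties are already broken in
#' the ranking (score_min, then alphabetically).
#'
#' @param scores A \code{\link{preference_scores}} data.frame.
#' @param n_risk,n_protective Group sizes; the "broad" published profile is
#'   9/9 (with 2 intermediate).
#' @return The scores data.frame with a \code{class} column.
#' @export
classify <- function(scores, n_risk = 9L, n_protective = 9L) {
  stopifnot(n_risk + n_protective <= 20L)
  cl <- rep("intermediate", nrow(scores))
  if (n_risk > 0) cl[seq_len(n_risk)] <- "risk"
  if (n_protective > 0)
    cl[seq(nrow(scores) - n_protective + 1L, nrow(scores))] <- "protective"
  scores$class <- cl
  scores
}

#' Overlap of observed residues with a predicted set
#'
#' Counts how many observed one-letter residues (with multiplicity) fall
#' inside a predicted set, along with the expectation under a random
#' 20-letter draw.
#'
#' @param predicted_set Character vector of one-letter codes.
#' @param observed_residues Character vector (may repeat).
#' @return list(count, expected).
#' @export
overlap_count <- function(predicted_set, observed_residues) {
  stopifnot(length(observed_residues) >= 1)
  list(count = sum(observed_residues %in% predicted_set),
       expected = length(observed_residues) * length(unique(predicted_set)) / 20)
}

# EMBOSS pKa values for the ionizable groups
PKA <- list(pos = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
            neg = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

net_charge_at <- function(counts, pH) {
  pos <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(pos) <- c("Nterm", "K", "R", "H")
  neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(neg) <- c("Cterm", "D", "E", "C", "Y")
  sum(pos / (1 + 10^(pH - PKA$pos[names(pos)]))) -
    sum(neg / (1 + 10^(PKA$neg[names(neg)] - pH)))
}

#' Charge and isoelectric-point profile of a protein
#'
#' Net charge from Henderson-Hasselbalch over the ionizable groups
#' (D, E, C, Y, H, K, R and the termini; EMBOSS pKa set), isoelectric
#' point by bisection on the monotone charge-pH curve, and basic/acidic
#' residue counts. Charge per residue is net charge divided by length.
#'
#' @param sequence One-letter amino-acid string (strictly the 20 codes).
#' @param pH pH at which charge is reported (default 7.0).
#' @param name Optional protein name.
#' @return list of class \code{protein_record}: name, sequence, length,
#'   counts/fractions of R, K, D, E, charge, charge_per_residue, pI.
#' @export
protein_profile <- function(sequence, pH = 7.0, name = NA_character_) {
  sequence <- toupper(gsub("\\s", "", sequence))
  letters_seq <- strsplit(sequence, "")[[1]]
  bad <- which(!letters_seq %in% AA1)
  if (length(bad))
    stop("invalid residues at positions: ", paste(bad, collapse = ", "))
  counts <- table(factor(letters_seq, levels = AA1))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  L <- length(letters_seq)
  q <- net_charge_at(counts, pH)
  pi_val <- stats::uniroot(function(x) net_charge_at(counts, x),
                           c(0, 14), tol = 1e-4)$root
  structure(list(
    name = name, sequence = sequence, length = L,
    n_R = counts[["R"]], n_K = counts[["K"]],
    n_D = counts[["D"]], n_E = counts[["E"]],
    frac_R = counts[["R"]] / L, frac_K = counts[["K"]] / L,
    frac_D = counts[["D"]] / L, frac_E = counts[["E"]] / L,
    pH = pH, charge = q, charge_per_residue = q / L,
    pI = pi_val), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa, charge %.2f at pH %.1f (%.4f/residue), pI %.2f\n",
              ifelse(is.na(x$name), "(unnamed)", x$name), x$length,
              x$charge, x$pH, x$charge_per_residue, x$pI))
  invisible(x)
}

#' Poly-citrullination model
#'
#' Replaces every arginine by glutamine (citrulline's closest natural
#' analogue: the positive charge is removed, the side-chain stays polar)
#' and recomputes the profile. Idempotent.
#'
#' @param record A \code{protein_record}.
#' @return The citrullinated \code{protein_record}.
#' @export
citrullinate <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  protein_profile(gsub("R", "Q", record$sequence, fixed = TRUE),
                  pH = record$pH,
                  name = if (is.na(record$name)) NA_character_ else
                    paste0(record$name, "_citrullinated"))
}

#' Profile every sequence of a FASTA file
#'
#' @param path FASTA of protein sequences.
#' @param pH Reporting pH.
#' @param citrullinated Also profile the poly-citrullinated forms.
#' @return data.frame, one row per protein (two with
#'   \code{citrullinated = TRUE}).
#' @export
profile_fasta <- function(path, pH = 7.0, citrullinated = FALSE) {
  seqs <- Biostrings::readAAStringSet(path)
  rows <- lapply(seq_along(seqs), function(i) {
    rec <- protein_profile(as.character(seqs[[i]]), pH = pH,
                           name = names(seqs)[i])
    recs <- list(rec)
    if (citrullinated) recs <- c(recs, list(citrullinate(rec)))
    do.call(rbind, lapply(recs, function(r)
      data.frame(name = r$name, length = r$length, n_R = r$n_R, n_K = r$n_K,
                 n_D = r$n_D, n_E = r$n_E, charge = r$charge,
                 charge_per_residue = r$charge_per_residue, pI = r$pI,
                 stringsAsFactors = FALSE)))
  })
  do.call(rbind, rows)
}
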