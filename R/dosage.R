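#' Construct a dosage matrix object
#'
#' Container pairing a marker table with an individuals-by-markers dosage
#' matrix (imputed allelic dosages in [0, 2]).
#'
#' @param dosage Numeric matrix, individuals in rows, markers in columns;
#'   column names are marker ids, row names individual ids.
#' @param r2 Numeric vector of per-marker imputation quality (squared
#'   correlation with the true genotype), in [0, 1].
#' @return An object of class \code{hla_dosage}: a list with elements
#'   \code{markers} (parsed marker table with an \code{r2} column),
#'   \code{dosage} and \code{individuals}.
#' @export
hla_dosage <- function(dosage, r2) {
  stopifnot(is.matrix(dosage), length(r2) == ncol(dosage))
  if (ncol(dosage) > 0 && is.null(colnames(dosage)))
    stop("dosage matrix must carry marker ids as column names")
  if (anyDuplicated(colnames(dosage)))
    stop("duplicate marker ids in dosage matrix")
  if (any(dosage < 0 | dosage > 2))
    stop("dosage outside [0,2]")
  if (any(r2 < 0 | r2 > 1)) stop("imputation r2 outside [0,1]")
  markers <- parse_marker_id(as.character(colnames(dosage)))
  markers$r2 <- as.numeric(r2)
  structure(list(markers = markers, dosage = dosage,
                 individuals = rownames(dosage)),
            class = "hla_dosage")
}

#' @export
print.hla_dosage <- function(x, ...) {
  cat("<hla_dosage> ", length(x$individuals), " individuals x ",
      nrow(x$markers), " markers (",
      paste(names(table(x$markers$kind)), table(x$markers$kind),
            sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read a dosage file
#'
#' The dosage dialect is TSV with header \code{marker r2 <ind1> <ind2> ...}
#' and one row per marker; dosages are printed with 3 decimals.
#'
#' @param path File path.
#' @param panel Optional \code{hla_panel}; when given, the file's individual
#'   columns must match \code{panel$individual_id} exactly (order included).
#' @return An \code{hla_dosage}.
#' @export
read_dosage <- function(path, panel = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || names(tab)[1] != "marker" || names(tab)[2] != "r2")
    stop("not a dosage file (expect header 'marker r2 <individuals...>'): ", path)
  inds <- names(tab)[-(1:2)]
  if (!is.null(panel)) {
    if (!identical(inds, panel$individual_id))
      stop("individuals in dosage file do not match panel")
  }
  d <- t(as.matrix(tab[, -(1:2), drop = FALSE]))
  colnames(d) <- tab$marker
  rownames(d) <- inds
  storage.mode(d) <- "double"
  hla_dosage(d, tab$r2)
}

#' Write a dosage file
#'
#' Inverse of \code{\link{read_dosage}}; canonical formatting (3 decimals for
#' dosages and imputation r2) so that read-write round-trips are exact.
#'
#' @param dm An \code{hla_dosage}.
#' @param path Output path.
#' @export
write_dosage <- function(dm, path) {
  stopifnot(inherits(dm, "hla_dosage"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("marker", "r2", dm$individuals), collapse = "\t"), con)
  for (j in seq_len(ncol(dm$dosage))) {
    writeLines(paste(c(colnames(dm$dosage)[j], sprintf("%.3f", dm$markers$r2[j]),
                       sprintf("%.3f", dm$dosage[, j])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Carrier frequency of each marker
#'
#' Fraction of individuals carrying at least one copy (dosage >= 0.5).
#' @param dm An \code{hla_dosage}.
#' @return Named numeric vector.
#' @export
carrier_freq <- function(dm) {
  colMeans(dm$dosage >= 0.5)
}

#' Filter markers on imputation quality and frequency
#'
#' Retains markers with imputation r2 strictly greater than \code{r2_min}
#' (the strict inequality mirrors standard post-imputation practice) and
#' carrier frequency at least \code{freq_min}; marker order is preserved.
#'
#' @param dm An \code{hla_dosage}.
#' @param r2_min Imputation-quality floor (strict), default 0.7.
#' @param freq_min Carrier-frequency floor, default 0.005 (guards logistic
#'   fits against quasi-separation from very rare residues).
#' @return Filtered \code{hla_dosage} (possibly with zero markers).
#' @export
filter_markers <- function(dm, r2_min = 0.7, freq_min = 0.005) {
  stopifnot(inherits(dm, "hla_dosage"), r2_min >= 0, r2_min <= 1)
  keep <- dm$markers$r2 > r2_min & carrier_freq(dm) >= freq_min
  subset_dosage(dm, keep)
}

subset_dosage <- function(dm, keep) {
  d <- dm$dosage[, keep, drop = FALSE]
  hla_dosage(d, dm$markers$r2[keep])
}

#' Group amino-acid residue markers into positions
#'
#' One group per (gene, protein position) with at least two observed
#' residues; the reference residue is the most frequent one (highest mean
#' dosage), ties broken alphabetically. Monomorphic positions are dropped.
#'
#' @param dm An \code{hla_dosage} containing AA markers.
#' @return A list of \code{aa_position} objects, each a list with
#'   \code{gene}, \code{aa_pos}, \code{marker_ids}, \code{residues} and
#'   \code{reference} (the reference residue's marker id).
#' @export
group_positions <- function(dm) {
  m <- dm$markers
  is_aa <- m$kind == "AA"
  if (!any(is_aa)) return(list())
  key <- paste(m$gene[is_aa], m$aa_pos[is_aa], sep = "_")
  idx <- split(which(is_aa), key)
  out <- list()
  for (k in names(idx)) {
    ids <- m$id[idx[[k]]]
    if (length(ids) < 2L) next
    mu <- colMeans(dm$dosage[, ids, drop = FALSE])
    ord <- order(-mu, m$residue[idx[[k]]])
    ref <- ids[ord[1]]
    pos <- list(gene = m$gene[idx[[k]][1]], aa_pos = m$aa_pos[idx[[k]][1]],
                marker_ids = ids, residues = m$residue[idx[[k]]],
                reference = ref)
    class(pos) <- "aa_position"
    out[[k]] <- pos
  }
  # order by gene then protein position
  ord <- order(vapply(out, `[[`, "", "gene"),
               vapply(out, `[[`, 0L, "aa_pos"))
  out[ord]
}

#' @export
print.aa_position <- function(x, ...) {
  cat("<aa_position> ", x$gene, "-", x$aa_pos, ": ",
      paste(x$residues, collapse = "/"),
      " (ref ", x$residues[x$marker_ids == x$reference], ")\n", sep = "")
  invisible(x)
}

#' Read or write a phenotype/covariate panel
#'
#' TSV with columns \code{individual_id}, \code{status} (0/1),
#' \code{sex} (male = 0, female = 1), \code{pc1..pc3}, \code{cohort}, then
#' optional autoantibody columns coded 0/1/NA (e.g. nRNP, Ro, La, Sm,
#' dsDNA, ACL).
#'
#' @param path File path.
#' @return A data.frame of class \code{hla_panel}.
#' @export
read_panel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_panel(p)
}

#' @rdname read_panel
#' @param panel An \code{hla_panel}.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_panel
#' @param x A data.frame with the panel columns.
#' @export
as_panel <- function(x) {
  need <- c("individual_id", "status", "sex", "pc1", "pc2", "pc3", "cohort")
  if (!all(need %in% names(x)))
    stop("panel missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  if (any(!x$status %in% c(0, 1) & !is.na(x$status)))
    stop("status must be 0/1")
  class(x) <- c("hla_panel", "data.frame")
  x
}

#' Antibody column names present in a panel
#' @param panel An \code{hla_panel}.
#' @export
panel_antibodies <- function(panel) {
  setdiff(names(panel),
          c("individual_id", "status", "sex", "pc1", "pc2", "pc3", "cohort"))
}

#' Read or write an allele-to-protein translation table
#'
#' CSV with columns \code{gene}, \code{allele} (4-digit code such as
#' \code{"15:01"}), \code{aa_pos}, \code{residue}; each
#' (gene, allele, aa_pos) maps to exactly one residue.
#'
#' @param path File path.
#' @return data.frame of class \code{allele_protein_map}.
#' @export
read_allele_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_allele_map(m)
}

#' @rdname read_allele_map
#' @param map An \code{allele_protein_map}.
#' @export
write_allele_map <- function(map, path) {
  utils::write.csv(map, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_allele_map
#' @param x data.frame with map columns.
#' @export
as_allele_map <- function(x) {
  need <- c("gene", "allele", "aa_pos", "residue")
  if (!all(need %in% names(x)))
    stop("allele map missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  if (anyDuplicated(x[, c("gene", "allele", "aa_pos")]))
    stop("allele map: duplicate (gene, allele, aa_pos) entries")
  class(x) <- c("allele_protein_map", "data.frame")
  x
}
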