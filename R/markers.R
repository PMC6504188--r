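HLA_GENES <- c("A", "B", "C", "DPA1", "DPB1", "DQA1", "DQB1", "DRB1")

#' Parse a SNP2HLA-style marker identifier
#'
#' Decodes the marker naming dialect used by SNP2HLA imputation output:
#' \itemize{
#'   \item \code{AA_<gene>_<aaPos>_<bp>_<res>}: amino-acid residue presence
#'     marker (\code{res} is a one-letter code, or \code{"x"} for an
#'     absence/indel grouping);
#'   \item \code{HLA_<gene>_<4 digits>}: 4-digit classical allele;
#'   \item \code{HLA_<gene>_<2 digits>}: 2-digit allele group;
#'   \item \code{SNP_<gene>_<bp>} or \code{rs<digits>}: biallelic SNP.
#' }
#'
#' @param id Character vector of marker identifiers.
#' @return A data.frame with one row per id and columns \code{id},
#'   \code{kind} (one of \code{"SNP"}, \code{"ALLELE2D"}, \code{"ALLELE4D"},
#'   \code{"AA"}), \code{gene}, \code{genomic_pos} (1-based hg19 bp, NA for
#'   rs ids), \code{aa_pos} and \code{residue} (NA except for AA markers).
#' @examples
#' parse_marker_id("AA_DRB1_13_32660115_R")
#' parse_marker_id(c("HLA_DRB1_1501", "rs9271348"))
#' @export
parse_marker_id <- function(id) {
  stopifnot(is.character(id), all(nzchar(id)))
  n <- length(id)
  out <- data.frame(id = id, kind = rep(NA_character_, n),
                    gene = rep(NA_character_, n),
                    genomic_pos = rep(NA_integer_, n),
                    aa_pos = rep(NA_integer_, n),
                    residue = rep(NA_character_, n), stringsAsFactors = FALSE)
  for (i in seq_along(id)) {
    x <- id[i]
    if (grepl("^rs[0-9]+$", x)) {
      out$kind[i] <- "SNP"
      next
    }
    parts <- strsplit(x, "_", fixed = TRUE)[[1]]
    if (parts[1] == "AA") {
      if (length(parts) != 5L || !(parts[2] %in% HLA_GENES) ||
          !grepl("^[0-9]+$", parts[3]) || !grepl("^[0-9]+$", parts[4]) ||
          !grepl("^[A-Zx]$", parts[5]))
        stop("malformed AA marker id: '", x, "'")
      out$kind[i] <- "AA"
      out$gene[i] <- parts[2]
      out$aa_pos[i] <- as.integer(parts[3])
      out$genomic_pos[i] <- as.integer(parts[4])
      out$residue[i] <- parts[5]
    } else if (parts[1] == "HLA") {
      if (length(parts) != 3L || !(parts[2] %in% HLA_GENES) ||
          !grepl("^[0-9]{2}$|^[0-9]{4}$", parts[3]))
        stop("malformed HLA allele marker id: '", x, "'")
      out$kind[i] <- if (nchar(parts[3]) == 4L) "ALLELE4D" else "ALLELE2D"
      out$gene[i] <- parts[2]
    } else if (parts[1] == "SNP") {
      if (length(parts) != 3L || !(parts[2] %in% HLA_GENES) ||
          !grepl("^[0-9]+$", parts[3]))
        stop("malformed SNP marker id: '", x, "'")
      out$kind[i] <- "SNP"
      out$gene[i] <- parts[2]
      out$genomic_pos[i] <- as.integer(parts[3])
    } else {
      stop("unrecognized marker id prefix: '", parts[1], "' in '", x, "'")
    }
  }
  out
}

#' Classical-allele code of a 4-digit allele marker
#'
#' @param id 4-digit allele marker ids (e.g. \code{"HLA_DRB1_1501"}).
#' @return Character vector of colon-separated codes (e.g. \code{"15:01"}).
#' @export
allele_code <- function(id) {
  m <- parse_marker_id(id)
  if (any(m$kind != "ALLELE4D")) stop("not a 4-digit allele marker")
  digits <- sub("^HLA_[^_]+_", "", id)
  paste0(substr(digits, 1, 2), ":", substr(digits, 3, 4))
}
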