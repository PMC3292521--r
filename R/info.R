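# Knowledge-based (informational) contact potential: a 20 x 20 matrix
# U_ab of contact free energies summed over the residue pairs in
# contact. Folding uses the intra-molecular contact map (sequence
# separation > 4); binding the rectangular inter-molecular map.

#' Contact energy matrices
#'
#' `contact_matrix()` returns the matrix used by the informational
#' scores. The packaged default (`source = "toy"`) is a synthetic
#' hydrophobic-attraction model,
#' `U_ab = -(h_a h_b) / h_max^2 + 0.1 q_a q_b`,
#' built from the shipped hydropathy and charge parameters: contacts
#' between hydrophobic residues are favorable, like charges in contact
#' are penalized and opposite charges rewarded. A published
#' residue-contact matrix can be supplied instead as a whitespace
#' separated file of 20 labeled rows and columns
#' (`read_contact_matrix()`); `write_contact_matrix()` emits that
#' format.
#'
#' @param source `"toy"` or a path to a matrix file.
#' @return A 20 x 20 symmetric numeric matrix with dimnames over the
#'   amino-acid alphabet, attribute `source`.
#' @export
contact_matrix <- function(source = "toy") {
  if (source == "toy") {
    p <- residue_params()
    u <- -outer(p$h, p$h) / max(p$h)^2 + 0.1 * outer(p$charge, p$charge)
    dimnames(u) <- list(p$aa, p$aa)
    attr(u, "source") <- "toy"
    return(u)
  }
  read_contact_matrix(source)
}

#' @rdname contact_matrix
#' @param file Path to a 20 x 20 labeled matrix file.
#' @export
read_contact_matrix <- function(file) {
  df <- utils::read.table(file, header = TRUE, check.names = FALSE,
                          comment.char = "#")
  u <- as.matrix(df)
  rownames(u) <- colnames(u)
  if (!all(AA_ALPHABET %in% rownames(u))) stop("matrix must cover all 20 amino acids")
  u <- u[AA_ALPHABET, AA_ALPHABET]
  if (max(abs(u - t(u))) > 1e-8) stop("contact matrix must be symmetric")
  attr(u, "source") <- file
  u
}

#' @rdname contact_matrix
#' @param u Matrix to write.
#' @export
write_contact_matrix <- function(u, file) {
  utils::write.table(round(u, 6), file, quote = FALSE, sep = "\t",
                     col.names = NA)
  invisible(file)
}

.aa_index <- function(sequence, context = "sequence") {
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) {
    stop("unknown residue letter(s) in ", context, ": ",
         paste(unique(aa[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Informational (knowledge-based) folding and binding scores
#'
#' `score_fold_info()` sums the contact energies `U[a_i, a_j]` over the
#' contacting residue pairs of an intra-molecular contact map;
#' `score_bind_info()` does the same over a rectangular inter-molecular
#' map, with rows indexed by the first molecule's sequence and columns
#' by the second's. Lower is better.
#'
#' @param sequence,seq1,seq2 Amino-acid strings.
#' @param cmap,inter_cmap A `contact_map` from [contact_map()] /
#'   [inter_contact_map()].
#' @param u Contact energy matrix from [contact_matrix()].
#' @return Numeric energy.
#' @export
score_fold_info <- function(sequence, cmap, u = contact_matrix()) {
  idx <- .aa_index(sequence)
  if (length(idx) != cmap$n) stop("sequence length does not match contact map")
  pairs <- which(cmap$contacts & upper.tri(cmap$contacts), arr.ind = TRUE)
  if (!nrow(pairs)) return(0)
  sum(u[cbind(idx[pairs[, 1]], idx[pairs[, 2]])])
}

#' @rdname score_fold_info
#' @export
score_bind_info <- function(seq1, seq2, inter_cmap, u = contact_matrix()) {
  i1 <- .aa_index(seq1, "seq1"); i2 <- .aa_index(seq2, "seq2")
  cm <- inter_cmap$contacts
  if (nrow(cm) != length(i1) || ncol(cm) != length(i2)) {
    stop("contact map dimensions do not match sequence lengths")
  }
  pairs <- which(cm, arr.ind = TRUE)
  if (!nrow(pairs)) return(0)
  sum(u[cbind(i1[pairs[, 1]], i2[pairs[, 2]])])
}
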