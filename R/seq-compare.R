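# Ortholog sequence comparison: global pairwise alignment, enumeration of
# substituted positions (labels such as "I35V" use the first sequence's
# 1-based numbering with its residue printed first), and residue polarity
# classification.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.validate_protein <- function(seq, label) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% .aa_alphabet)
  if (length(bad))
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " in ", label, call. = FALSE)
  paste(chars, collapse = "")
}

#' Globally align two ortholog protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gaps
#' (deterministic highest-scoring alignment).
#'
#' @param seq_a,seq_b One-letter amino-acid strings (validated alphabet).
#' @param labels Names of the two orthologs.
#' @param gap_opening,gap_extension Affine gap penalties, defaults 10 / 0.5.
#' @return An object of class \code{ortholog_pair} with the aligned strings
#'   and the per-column index map.
#' @export
align_pair <- function(seq_a, seq_b, labels = c("seq_a", "seq_b"),
                       gap_opening = 10, gap_extension = 0.5) {
  seq_a <- .validate_protein(seq_a, labels[1])
  seq_b <- .validate_protein(seq_b, labels[2])
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty", call. = FALSE)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = data_env$BLOSUM62, type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension)
  a <- as.character(Biostrings::alignedPattern(aln))
  b <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos_a <- cumsum(ca != "-"); pos_a[ca == "-"] <- NA
  pos_b <- cumsum(cb != "-"); pos_b[cb == "-"] <- NA
  structure(list(seq_a = seq_a, seq_b = seq_b, labels = labels,
                 aligned_a = a, aligned_b = b,
                 map = data.frame(column = seq_along(ca), a = ca, b = cb,
                                  pos_a = pos_a, pos_b = pos_b,
                                  stringsAsFactors = FALSE),
                 score = Biostrings::score(aln)),
            class = "ortholog_pair")
}

#' @export
print.ortholog_pair <- function(x, ...) {
  n_mis <- sum(x$map$a != x$map$b & x$map$a != "-" & x$map$b != "-")
  n_gap <- sum(x$map$a == "-" | x$map$b == "-")
  cat("Pairwise alignment", x$labels[1], "vs", x$labels[2], ":",
      nrow(x$map), "columns,", n_mis, "substitutions,", n_gap,
      "gap columns (score", format(x$score), ")\n")
  invisible(x)
}

#' Enumerate substitutions between two aligned orthologs
#'
#' One record per aligned mismatch; gap columns are reported separately in
#' the \code{gaps} attribute. Labels use the first sequence's numbering with
#' its residue first (e.g. "I35V").
#'
#' @param pair An \code{ortholog_pair} from \code{\link{align_pair}}.
#' @return A data.frame with columns \code{position} (1-based on seq_a),
#'   \code{from_res}, \code{to_res}, \code{label}, \code{class_from},
#'   \code{class_to}.
#' @export
enumerate_substitutions <- function(pair) {
  stopifnot(inherits(pair, "ortholog_pair"))
  m <- pair$map
  mis <- m[m$a != m$b & m$a != "-" & m$b != "-", ]
  out <- data.frame(position = mis$pos_a,
                    from_res = mis$a, to_res = mis$b,
                    label = paste0(mis$a, mis$pos_a, mis$b),
                    class_from = vapply(mis$a, classify_residue, character(1)),
                    class_to = vapply(mis$b, classify_residue, character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "gaps") <- m[m$a == "-" | m$b == "-", ]
  out
}

.default_polarity <- c(
  D = "acidic", E = "acidic",
  K = "basic", R = "basic", H = "basic",
  S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
  Y = "polar", G = "polar",
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
  I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
  W = "hydrophobic", P = "hydrophobic")

#' Polarity class of a residue
#'
#' Default mapping: D,E acidic; K,R,H basic; S,T,N,Q,C,Y,G polar;
#' A,V,L,I,M,F,W,P hydrophobic. Glycine and histidine assignments vary by
#' convention, so the mapping can be overridden.
#'
#' @param code One-letter residue code.
#' @param mapping Named character vector overriding the default table.
#' @return One of "acidic", "basic", "polar", "hydrophobic".
#' @export
classify_residue <- function(code, mapping = .default_polarity) {
  code <- toupper(code)
  if (!code %in% names(mapping))
    stop("nonstandard residue code '", code, "'", call. = FALSE)
  unname(mapping[code])
}

#' Synthetic ortholog pair emulating the two PMI sequences
#'
#' A fully synthetic 161-residue sequence pair (NOT the deposited
#' structures' sequences) differing at 16 positions with the substitution
#' labels of the published Tba/Tko phosphomannose-isomerase comparison (E7N,
#' F8L, A17L, I35V, P42K, K48R, Q59E, K61R, E65G, E66D, R67T, D70Q, K90E,
#' E92D, I100V, F105H), for exercising the alignment and enumeration
#' machinery offline.
#'
#' @return A list with elements \code{seq_a} (Tba-like), \code{seq_b}
#'   (Tko-like) and \code{substitutions} (the planted label set).
#' @export
synthetic_pmi_pair <- function() {
  n <- 161
  base <- rep(strsplit("GAVLSTNQKEDRHIFMPWYC", "")[[1]], length.out = n)
  planted <- c("E7N", "F8L", "A17L", "I35V", "P42K", "K48R", "Q59E",
               "K61R", "E65G", "E66D", "R67T", "D70Q", "K90E", "E92D",
               "I100V", "F105H")
  pos <- as.integer(gsub("[A-Z]", "", planted))
  from <- substr(planted, 1, 1)
  to <- substr(planted, nchar(planted), nchar(planted))
  a <- base
  # conserved active site of the worked example
  a[c(44, 46, 85)] <- "H"; a[51] <- "E"
  a[pos] <- from
  b <- a
  b[pos] <- to
  list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
       substitutions = planted)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(names(seqs)) == length(seqs))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con, sep = "\n")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (single-line or wrapped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
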