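# Topology: residue sequence + atom table shared by every frame of an ensemble.

#' Build a chain topology from a one-letter sequence
#'
#' A topology holds the residue sequence, author residue numbering and the
#' per-frame atom layout of an ensemble.  Two backbone layouts are supported:
#' a C-alpha trace (one CA atom per residue) and a minimal N-CA-C backbone.
#'
#' @param sequence One-letter amino-acid sequence (single string or character
#'   vector of single letters).
#' @param first_resno Author number of the first residue (default 1).
#' @param chain_id Single chain identifier (default `"A"`).
#' @param backbone_mode `"CA-only"` (default) or `"N-CA-C"`.
#' @return An object of class `"topology"`: a list with `chain_id`,
#'   `resno` (integer, strictly increasing), `resid` (three-letter codes) and
#'   `atoms`, a data frame with columns `elety` (atom name), `res_index`
#'   (1-based index into the residue list) and `element`.
#' @examples
#' top <- topology("MEEPQ")
#' n_residues(top)
#' @export
topology <- function(sequence, first_resno = 1L, chain_id = "A",
                     backbone_mode = c("CA-only", "N-CA-C")) {
  backbone_mode <- match.arg(backbone_mode)
  seq1 <- toupper(unlist(strsplit(paste(sequence, collapse = ""), "")))
  if (length(seq1) < 1L)
    stop("sequence must contain at least one residue")
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (any(!seq1 %in% standard))
    stop("unrecognized one-letter code in sequence: ",
         paste(unique(seq1[!seq1 %in% standard]), collapse = ", "))
  resid3 <- bio3d::aa123(seq1)
  n <- length(seq1)
  per_res <- switch(backbone_mode,
    "CA-only" = data.frame(elety = "CA", element = "C",
                           stringsAsFactors = FALSE),
    "N-CA-C"  = data.frame(elety = c("N", "CA", "C"),
                           element = c("N", "C", "C"),
                           stringsAsFactors = FALSE))
  atoms <- data.frame(
    elety = rep(per_res$elety, times = n),
    res_index = rep(seq_len(n), each = nrow(per_res)),
    element = rep(per_res$element, times = n),
    stringsAsFactors = FALSE)
  structure(list(chain_id = chain_id,
                 resno = as.integer(first_resno + seq_len(n) - 1L),
                 resid = unname(resid3),
                 atoms = atoms),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("Topology: chain", x$chain_id, "-", n_residues(x), "residues,",
      nrow(x$atoms), "atoms/frame\n")
  cat("  residues", x$resno[1], "-", x$resno[n_residues(x)], "\n")
  cat("  sequence:", sequence_string(x), "\n")
  invisible(x)
}

#' Number of residues in a topology or ensemble
#' @param x A `topology` or `ensemble` object.
#' @return Integer count of residues.
#' @export
n_residues <- function(x) {
  if (inherits(x, "ensemble")) x <- x$topology
  length(x$resno)
}

#' One-letter sequence of a topology
#' @param x A `topology` or `ensemble` object.
#' @return Single string of one-letter codes.
#' @export
sequence_string <- function(x) {
  if (inherits(x, "ensemble")) x <- x$topology
  paste(bio3d::aa321(x$resid), collapse = "")
}

validate_topology <- function(top) {
  stopifnot(inherits(top, "topology"))
  if (any(diff(top$resno) <= 0L))
    stop("topology residue numbers must be strictly increasing")
  if (any(top$atoms$res_index < 1L | top$atoms$res_index > length(top$resno)))
    stop("topology atom table references residues out of range")
  invisible(top)
}

# map author residue numbers -> residue index, with a clear error
res_index_of <- function(top, resno) {
  idx <- match(resno, top$resno)
  if (anyNA(idx))
    stop("residue number(s) not present in topology: ",
         paste(resno[is.na(idx)], collapse = ", "))
  idx
}

#' Wild-type p53 transactivation domain topology (residues 1-61)
#'
#' The 61-residue transactivation domain (TAD) of human tumor suppressor p53,
#' an intrinsically disordered region carrying three transient helices
#' (residues 18-27, 40-44 and 48-52).  This is the reference sequence used
#' throughout the package examples and by the synthetic-ensemble presets.
#'
#' @param backbone_mode Atom layout, `"CA-only"` (default) or `"N-CA-C"`.
#' @return A `topology` for residues 1-61 of p53.
#' @examples
#' top <- p53_tad_fixture()
#' substr(sequence_string(top), 24, 24)  # "K", the K24N mutation site
#' @export
p53_tad_fixture <- function(backbone_mode = c("CA-only", "N-CA-C")) {
  topology("MEEPQSDPSVEPPLSQETFSDLWKLLPENNVLSPLPSQAMDDLMLSPDDIEQWFTEDPGPD",
           first_resno = 1L, backbone_mode = match.arg(backbone_mode))
}

#' Apply point mutations to a topology
#'
#' Relabels residues of a topology at the sequence level; coordinates and the
#' atom layout are untouched.  Mutations are given either in standard
#' `"K24N"` notation (wild-type letter, author residue number, new letter) in
#' which case the wild-type letter is checked against the topology, or as a
#' list of `(position, new_letter)` pairs.
#'
#' @param top A `topology`.
#' @param mutations Character vector like `c("K24N", "N30D")`, or a list of
#'   `list(position, new_letter)` pairs.  All mutations are applied
#'   atomically: any failed check leaves the topology unmodified.
#' @return The mutated `topology`.
#' @examples
#' mut <- apply_point_mutations(p53_tad_fixture(), c("N29K", "N30D"))
#' substr(sequence_string(mut), 29, 30)
#' @export
apply_point_mutations <- function(top, mutations) {
  validate_topology(top)
  if (is.character(mutations)) {
    parsed <- lapply(mutations, parse_mutation)
  } else {
    parsed <- lapply(mutations, function(m)
      list(from = NA_character_, pos = as.integer(m[[1]]),
           to = toupper(as.character(m[[2]]))))
  }
  new_resid <- top$resid
  seq1 <- bio3d::aa321(top$resid)
  for (m in parsed) {
    idx <- res_index_of(top, m$pos)
    if (!is.na(m$from) && seq1[idx] != m$from)
      stop(sprintf(
        "mutation %s%d%s: topology has %s at position %d, not %s",
        m$from, m$pos, m$to, seq1[idx], m$pos, m$from))
    if (!m$to %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
      stop("unrecognized target residue letter: ", m$to)
    new_resid[idx] <- bio3d::aa123(m$to)
    seq1[idx] <- m$to   # later mutations see the edited sequence
  }
  top$resid <- new_resid
  top
}

parse_mutation <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", s))[[1]]
  if (length(m) != 4L)
    stop("cannot parse mutation string: '", s,
         "' (expected e.g. \"K24N\")")
  list(from = toupper(m[2]), pos = as.integer(m[3]), to = toupper(m[4]))
}
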