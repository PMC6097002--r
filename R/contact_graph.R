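# Inter-strand beta-contact detection and the system BB matrix.

#' Beta-contact distance window
#'
#' The typical center-of-mass distance between hydrogen-bonded backbone
#' groups of adjacent beta-strands is 4.7-5.3 Angstrom; two backbone grains
#' on different strands at a distance inside this closed window form a
#' beta-contact.
#'
#' @param r_min Lower bound, Angstrom.
#' @param r_max Upper bound, Angstrom.
#' @return Object of class `contact_range`.
#' @export
contact_range <- function(r_min = 4.7, r_max = 5.3) {
  if (!(r_min > 0 && r_min < r_max))
    stop("contact range requires 0 < r_min < r_max")
  structure(list(r_min = r_min, r_max = r_max), class = "contact_range")
}

#' Beta-contact indicator
#'
#' Returns 1 when a distance lies inside the closed contact window
#' `[r_min, r_max]`, 0 otherwise.  Vectorized over `r_ij`.
#'
#' @param r_ij Distance(s) in Angstrom, non-negative.
#' @param range A [contact_range].
#' @return Integer 0/1 vector.
#' @export
beta_contact <- function(r_ij, range = contact_range()) {
  if (any(r_ij < 0)) stop("distances must be non-negative")
  as.integer(r_ij >= range$r_min & r_ij <= range$r_max)
}

# All-pairs distance matrix, minimum-image when an orthorhombic box is given.
pairwise_distances <- function(coords, box = NULL) {
  if (is.null(box)) return(as.matrix(stats::dist(coords)))
  n <- nrow(coords)
  d2 <- matrix(0, n, n)
  for (dim in 1:3) {
    dx <- outer(coords[, dim], coords[, dim], "-")
    dx <- dx - box[dim] * round(dx / box[dim])
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}

#' Build the system BB matrix of beta-contacts
#'
#' The BB matrix is the binary `(S*SL) x (S*SL)` matrix whose entry (i, j) is
#' 1 when grains i and j belong to different strands and are within the
#' beta-contact window.  Same-strand pairs are always 0 (contacts are
#' inter-strand only), as are pairs involving unassigned trailing grains.
#' Distances use the minimum-image convention when the frame has a box.
#'
#' @param frame A [backbone_frame]; the first `S*SL` grains (per the strand
#'   partition) are analyzed.
#' @param topology A [system_topology].
#' @param range A [contact_range].
#' @param strand_of Optional precomputed strand assignment (as from
#'   [partition_strands]); defaults to the contiguous partition with the
#'   topology's chain breaks.
#' @return Object of class `bb_matrix`: the binary matrix with the topology
#'   and strand assignment attached as attributes.
#' @export
build_bb_matrix <- function(frame, topology, range = contact_range(),
                            strand_of = NULL) {
  n <- nrow(frame$coords)
  if (is.null(strand_of))
    strand_of <- partition_strands(n, topology$n_strands,
                                   topology$strand_length,
                                   topology$chain_breaks)
  if (length(strand_of) != n)
    stop("strand assignment length does not match frame")
  d <- pairwise_distances(frame$coords, frame$box)
  bb <- matrix(0L, n, n)
  bb[d >= range$r_min & d <= range$r_max] <- 1L
  same <- outer(strand_of, strand_of, "==")
  same[is.na(same)] <- TRUE   # unassigned grains carry no contacts
  bb[same] <- 0L
  diag(bb) <- 0L
  structure(bb, class = c("bb_matrix", "matrix"),
            topology = topology, strand_of = strand_of, range = range)
}

#' Extract the strand-pair contact submatrix
#'
#' The `SL x SL` block of the BB matrix for strands `p` (rows, in-strand
#' order) and `q` (columns).  `pair_submatrix(bb, p, q)` is the transpose of
#' `pair_submatrix(bb, q, p)`.
#'
#' @param bb A `bb_matrix` from [build_bb_matrix].
#' @param p,q Distinct strand indices (1-based).
#' @return Binary `SL x SL` matrix.
#' @export
pair_submatrix <- function(bb, p, q) {
  top <- attr(bb, "topology")
  strand_of <- attr(bb, "strand_of")
  S <- top$n_strands
  if (p == q) stop("p and q must be different strands")
  if (p < 1L || p > S || q < 1L || q > S) stop("strand index out of range")
  gi <- which(strand_of == p)
  gj <- which(strand_of == q)
  unclass(bb)[gi, gj, drop = FALSE]
}

#' Dump a BB matrix as a sparse triplet CSV
#'
#' Writes rows `i,j,1` (1-based grain indices, upper triangle) for debugging
#' and external inspection.
#'
#' @param bb A `bb_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bb_triplets <- function(bb, path) {
  idx <- which(unclass(bb) == 1L & upper.tri(bb), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], value = 1L)
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
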