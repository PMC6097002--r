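# Beta-sheet reconstruction via the triplet continuity heuristic, and the
# %Ms beta-strand percentage.
#
# A sheet is seeded by a triplet of strands (a, b, c) with b central: both
# pairs must be matched beta-interactions in the P matrix, and the same
# portion of b must form at least `min_contacts` beta-contacts with each of
# a and c.  Qualifying triplets sharing a strand are merged into sheets.

#' Row/column reduction vectors of a strand triplet
#'
#' Reduces the BB-matrix areas of the two strand pairs of a triplet to count
#' vectors along the central strand `b`: `v_r[j]` is the number of
#' beta-contacts between grain `j` of `b` and any grain of `a`; `v_c[j]` the
#' same versus `c`.
#'
#' @param bb A `bb_matrix`.
#' @param p_mat A `p_matrix` for the same system.
#' @param a,b,c Strand indices; pairs (a,b) and (b,c) must be non-null in
#'   the P matrix.
#' @return List with numeric vectors `v_r` and `v_c`, each of length SL.
#' @export
pair_reduction_vectors <- function(bb, p_mat, a, b, c) {
  if (is.null(p_entry(p_mat, a, b)) || is.null(p_entry(p_mat, b, c)))
    stop("triplet requires non-null P entries for (a,b) and (b,c)")
  list(v_r = rowSums(pair_submatrix(bb, b, a)),
       v_c = rowSums(pair_submatrix(bb, b, c)))
}

#' Projection of the two reduction vectors and its residue extent
#'
#' The projection is the elementwise product of `v_r` and `v_c`: non-zero
#' where the central strand contacts both neighbours at the same residue.
#' The extent is the inclusive index span from the first to the last
#' non-zero element of the projection — the number of consecutive central
#' strand residues bracketing the doubly-contacted portion — or 0 when the
#' contacted portions are disjoint.
#'
#' @param v_r,v_c Equal-length count vectors.
#' @return List with `v_p` (elementwise product) and `extent` (integer).
#' @export
triplet_projection <- function(v_r, v_c) {
  if (length(v_r) != length(v_c))
    stop("reduction vectors differ in length")
  v_p <- v_r * v_c
  nz <- which(v_p != 0)
  extent <- if (!length(nz)) 0L else as.integer(max(nz) - min(nz) + 1L)
  list(v_p = v_p, extent = extent)
}

#' Does a strand triplet qualify as a beta-sheet seed?
#'
#' True when the central strand forms at least `min_contacts` contacts with
#' each neighbour and the doubly-contacted portion spans at least
#' `min_contacts` residues (extent of the projection).
#'
#' @inheritParams pair_reduction_vectors
#' @param min_contacts Minimum contacts / span (default 3).
#' @return Logical.
#' @export
qualify_triplet <- function(bb, p_mat, a, b, c, min_contacts = 3L) {
  v <- pair_reduction_vectors(bb, p_mat, a, b, c)
  if (sum(v$v_r) < min_contacts || sum(v$v_c) < min_contacts) return(FALSE)
  triplet_projection(v$v_r, v$v_c)$extent >= min_contacts
}

#' Reconstruct beta-sheets from the BB and P matrices
#'
#' Enumerates all strand triplets (a, b, c) with `a < c` and both pairs
#' matched in the P matrix, keeps the qualifying ones, and merges triplets
#' sharing at least one strand into sheets (connected components).  A sheet
#' therefore always contains >= 3 strands; two-strand pairings remain
#' beta-interactions but are never counted as sheet membership.
#'
#' @param bb A `bb_matrix`.
#' @param p_mat A `p_matrix`.
#' @param min_contacts Qualification threshold (default 3).
#' @return Object of class `sheet_report`: list with `sheets` (each a list
#'   of `strands`, `extent` = max qualifying-triplet span, `triplets`),
#'   `n_beta_strands`, `percent_ms` and `S`.
#' @export
reconstruct_sheets <- function(bb, p_mat, min_contacts = 3L) {
  S <- p_mat$S
  e <- p_mat$entries
  # adjacency list of matched pairs
  partners <- vector("list", S)
  if (nrow(e)) for (r in seq_len(nrow(e))) {
    partners[[e$p[r]]] <- c(partners[[e$p[r]]], e$q[r])
    partners[[e$q[r]]] <- c(partners[[e$q[r]]], e$p[r])
  }
  triplets <- list()
  for (b in seq_len(S)) {
    nb <- sort(partners[[b]])
    if (length(nb) < 2L) next
    for (ia in seq_len(length(nb) - 1L)) {
      for (ic in (ia + 1L):length(nb)) {
        a <- nb[ia]; c <- nb[ic]
        v <- pair_reduction_vectors(bb, p_mat, a, b, c)
        if (sum(v$v_r) < min_contacts || sum(v$v_c) < min_contacts) next
        ext <- triplet_projection(v$v_r, v$v_c)$extent
        if (ext < min_contacts) next
        triplets[[length(triplets) + 1L]] <-
          list(a = a, b = b, c = c, extent = ext)
      }
    }
  }
  sheets <- list()
  n_beta <- 0L
  if (length(triplets)) {
    # merge triplets sharing a strand: connected components of the
    # strand-membership graph
    tri_strands <- lapply(triplets, function(t) c(t$a, t$b, t$c))
    edges <- do.call(rbind, lapply(tri_strands, function(s)
      cbind(s[c(1, 2)], s[c(2, 3)])))
    g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                     directed = FALSE)
    comp <- igraph::components(g)
    member <- split(as.integer(igraph::V(g)$name), comp$membership)
    for (m in member) {
      strands <- sort(m)
      tri_in <- triplets[vapply(tri_strands,
                                function(s) all(s %in% strands), logical(1))]
      sheets[[length(sheets) + 1L]] <-
        list(strands = strands,
             extent = max(vapply(tri_in, function(t) t$extent, integer(1))),
             triplets = lapply(tri_in, function(t) c(t$a, t$b, t$c)))
    }
    sheets <- sheets[order(vapply(sheets, function(s) s$strands[1], integer(1)))]
    n_beta <- length(unique(unlist(lapply(sheets, function(s) s$strands))))
  }
  structure(list(sheets = sheets,
                 n_beta_strands = n_beta,
                 percent_ms = percent_ms(n_beta, S),
                 S = S),
            class = "sheet_report")
}

#' @export
print.sheet_report <- function(x, ...) {
  cat(sprintf("sheet_report: %d sheet(s), %d / %d strands in sheets, %%Ms = %d\n",
              length(x$sheets), x$n_beta_strands, x$S, x$percent_ms))
  for (i in seq_along(x$sheets))
    cat(sprintf("  sheet %d: %d strands (extent %d): %s\n", i,
                length(x$sheets[[i]]$strands), x$sheets[[i]]$extent,
                paste(x$sheets[[i]]$strands, collapse = ",")))
  invisible(x)
}

#' Beta-strand percentage (%Ms)
#'
#' `100 * n_beta_strands / S`, rounded to the nearest integer (ties
#' half-up): the fraction of strands belonging to reconstructed
#' beta-sheets.
#'
#' @param n_beta_strands Strands in any sheet.
#' @param S Total strands.
#' @return Integer percentage in \[0, 100\].
#' @export
percent_ms <- function(n_beta_strands, S) {
  if (S <= 0) stop("S must be positive")
  if (n_beta_strands < 0 || n_beta_strands > S)
    stop("n_beta_strands must lie in [0, S]")
  as.integer(floor(100 * n_beta_strands / S + 0.5))
}

#' Write a sheet report as JSON
#'
#' @param report A `sheet_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sheet_report <- function(report, path) {
  obj <- list(
    S = report$S,
    n_beta_strands = report$n_beta_strands,
    percent_ms = report$percent_ms,
    sheets = lapply(seq_along(report$sheets), function(i) {
      s <- report$sheets[[i]]
      list(id = i, strands = s$strands, extent = s$extent,
           triplets = s$triplets)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
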