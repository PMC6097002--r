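# Strand-registry assignment: shift-matrix template library, normalized
# cross-correlation matching, P matrix and shift profiles.
#
# Template convention (1-based indices; rows = grains of the lower-indexed
# strand p, columns = grains of q):
#   parallel, shift k:      T[i, j] = 1  iff  j = i + k
#   antiparallel, shift k:  T[i, j] = 1  iff  j = (SL + 1 - i) + k
# so parallel k = 0 is the identity pattern ("in-register") and antiparallel
# k = 0 is the exact reversal (anti-diagonal).  Positive k slides the partner
# strand toward higher column index.  A template for shift k has SL - |k|
# non-zero entries; |k| <= SL - 3 keeps at least 3 overlapping positions.

#' Build the shift-matrix template library
#'
#' Enumerates binary `SL x SL` templates for every alignment (orientation in
#' parallel/antiparallel, signed shift k with `|k| <= k_max`).  The library
#' is ordered by the deterministic tie-break priority used in matching:
#' smaller `|k|` first, parallel before antiparallel, positive k before
#' negative.
#'
#' @param SL Strand length (>= 3).
#' @param k_max Largest |shift| enumerated; default `SL - 3` (below 3
#'   overlapping positions no alignment is meaningful).
#' @return Object of class `shift_library`: list with `SL`, `k_max` and
#'   `templates`, a list of entries `(orientation, k, template)`.
#' @export
build_shift_library <- function(SL, k_max = SL - 3L) {
  SL <- as.integer(SL); k_max <- as.integer(k_max)
  if (SL < 3L) stop("SL must be >= 3")
  if (k_max < 0L || k_max > SL - 3L)
    stop("k_max must be in [0, SL - 3]")
  ks <- unique(as.integer(unlist(lapply(0:k_max, function(a)
    if (a == 0L) 0L else c(a, -a)))))
  templates <- list()
  for (k in ks) {
    for (orient in c("parallel", "antiparallel")) {
      tpl <- matrix(0L, SL, SL)
      i <- seq_len(SL)
      j <- if (orient == "parallel") i + k else (SL + 1L - i) + k
      ok <- j >= 1L & j <= SL
      tpl[cbind(i[ok], j[ok])] <- 1L
      templates[[length(templates) + 1L]] <-
        list(orientation = orient, k = k, template = tpl)
    }
  }
  structure(list(SL = SL, k_max = k_max, templates = templates),
            class = "shift_library")
}

#' Normalized cross-correlation of two binary matrices
#'
#' For binary matrices the NCC reduces to
#' `sum(a * b) / sqrt(sum(a) * sum(b))`: 1 iff the supports are identical,
#' 0 iff they are disjoint.  Undefined (returns `NULL`) when either matrix
#' is all zero.
#'
#' @param sub,template Equal-shape binary matrices.
#' @return A number in \[0, 1\], or `NULL` for an all-zero input.
#' @export
ncc <- function(sub, template) {
  if (!all(dim(sub) == dim(template)))
    stop("ncc: shape mismatch")
  sa <- sum(sub); sb <- sum(template)
  if (sa == 0 || sb == 0) return(NULL)
  sum(sub * template) / sqrt(sa * sb)
}

#' Match a strand-pair contact submatrix against the shift library
#'
#' Finds the alignment whose template maximizes the NCC with the contact
#' submatrix.  Ties (within 1e-12) are broken deterministically: smaller
#' `|k|`, then parallel before antiparallel, then positive before negative
#' shift.  The match is rejected (`NULL`) when the submatrix is all zero or
#' when the winning template explains fewer than `min_contacts` contacts —
#' the minimum H-bond count for a credible beta-pairing.
#'
#' @param sub Binary `SL x SL` contact submatrix (rows = first strand).
#' @param library A `shift_library` built for the same `SL`.
#' @param min_contacts Minimum template-consistent contacts (default 3).
#' @return `NULL`, or a list `(orientation, k, score, contacts)`.
#' @export
match_alignment <- function(sub, library, min_contacts = 3L) {
  if (!all(dim(sub) == c(library$SL, library$SL)))
    stop("submatrix shape does not match library SL")
  if (sum(sub) == 0) return(NULL)
  ssub <- sum(sub)
  scores <- vapply(library$templates, function(e)
    sum(sub * e$template) / sqrt(ssub * sum(e$template)), numeric(1))
  cand <- which(scores >= max(scores) - 1e-12)
  if (length(cand) > 1L) {  # explicit tie-break: |k|, then P, then +k
    ks <- vapply(library$templates[cand], function(e) e$k, integer(1))
    par <- vapply(library$templates[cand], function(e)
      e$orientation == "parallel", logical(1))
    cand <- cand[order(abs(ks), !par, ks < 0)]
  }
  best <- cand[1L]
  e <- library$templates[[best]]
  contacts <- sum(sub * e$template)
  if (contacts < min_contacts) return(NULL)
  list(orientation = e$orientation, k = e$k,
       score = scores[best], contacts = as.integer(contacts))
}

#' Build the strand potential beta-interaction (P) matrix
#'
#' Coarsens the BB contact matrix from grain level to strand level: every
#' unordered strand pair whose contact submatrix matches a shift template
#' with at least `min_contacts` consistent contacts becomes a "potential
#' beta-interaction" carrying its best (orientation, shift) alignment.
#'
#' @param bb A `bb_matrix` from [build_bb_matrix].
#' @param library Optional `shift_library`; built with default `k_max` from
#'   the topology when omitted.
#' @param min_contacts Minimum template-consistent contacts per pair.
#' @return Object of class `p_matrix`: list with `S`, `SL`, `min_contacts`
#'   and `entries`, a data.frame with one row per non-null unordered pair
#'   (columns p, q, orientation, k, score, contacts; p < q, rows of the
#'   matched submatrix indexed by strand p).
#' @export
build_p_matrix <- function(bb, library = NULL, min_contacts = 3L) {
  top <- attr(bb, "topology")
  S <- top$n_strands; SL <- top$strand_length
  if (is.null(library)) library <- build_shift_library(SL)
  if (library$SL != SL) stop("library SL does not match topology")
  entries <- list()
  # only pairs with any contact at all need matching
  strand_of <- attr(bb, "strand_of")
  for (p in seq_len(S - 1L)) {
    for (q in (p + 1L):S) {
      sub <- pair_submatrix(bb, p, q)
      if (!any(sub == 1L)) next
      m <- match_alignment(sub, library, min_contacts)
      if (is.null(m)) next
      entries[[length(entries) + 1L]] <-
        data.frame(p = p, q = q, orientation = m$orientation, k = m$k,
                   score = m$score, contacts = m$contacts,
                   stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries)
             else data.frame(p = integer(), q = integer(),
                             orientation = character(), k = integer(),
                             score = numeric(), contacts = integer(),
                             stringsAsFactors = FALSE)
  structure(list(S = S, SL = SL, min_contacts = as.integer(min_contacts),
                 entries = entries),
            class = "p_matrix")
}

#' @export
print.p_matrix <- function(x, ...) {
  cat(sprintf("p_matrix: %d strands, %d beta-interactions\n",
              x$S, nrow(x$entries)))
  if (nrow(x$entries)) print(utils::head(x$entries, 10))
  invisible(x)
}

#' Look up a P-matrix entry for an ordered strand pair
#'
#' Entry (q, p) is entry (p, q) with the shift convention adjusted: the
#' parallel shift negates on transposition, the antiparallel shift is
#' unchanged (the anti-diagonal pattern is symmetric in the pair order).
#'
#' @param p_mat A `p_matrix`.
#' @param p,q Strand indices.
#' @return `NULL` or list `(orientation, k, score, contacts)`.
#' @export
p_entry <- function(p_mat, p, q) {
  if (p == q) return(NULL)
  e <- p_mat$entries
  row <- e[e$p == min(p, q) & e$q == max(p, q), , drop = FALSE]
  if (!nrow(row)) return(NULL)
  k <- row$k
  if (p > q && row$orientation == "parallel") k <- -k
  list(orientation = row$orientation, k = as.integer(k),
       score = row$score, contacts = as.integer(row$contacts))
}

#' Number of beta-interactions in a P matrix
#'
#' @param p_mat A `p_matrix`.
#' @return Count of non-null unordered strand pairs.
#' @export
n_beta_interactions <- function(p_mat) nrow(p_mat$entries)

#' Shift profile: histogram of matched alignments
#'
#' Bins the non-null P-matrix entries by (orientation, shift).  The profile
#' is the standard registry summary for a structure or frame: a parallel
#' in-register sheet concentrates all mass at (parallel, 0).
#'
#' @param p_mat A `p_matrix`.
#' @return Object of class `shift_profile`: data.frame with columns
#'   orientation, shift, count, fraction (fractions sum to 1 when any
#'   interaction exists), plus attribute `total`.
#' @export
shift_profile <- function(p_mat) {
  e <- p_mat$entries
  if (!nrow(e)) {
    out <- data.frame(orientation = character(), shift = integer(),
                      count = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(e))),
                            by = list(orientation = e$orientation, shift = e$k),
                            FUN = sum)
    agg <- agg[order(agg$orientation, agg$shift), , drop = FALSE]
    out <- data.frame(orientation = agg$orientation, shift = agg$shift,
                      count = as.integer(agg$count),
                      fraction = agg$count / nrow(e),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  structure(out, class = c("shift_profile", "data.frame"),
            total = nrow(e))
}

#' Dominant orientation of a shift profile
#'
#' @param profile A `shift_profile`.
#' @return `"parallel"`, `"antiparallel"`, or `NA` for an empty profile.
#' @export
dominant_orientation <- function(profile) {
  if (!nrow(profile)) return(NA_character_)
  by_orient <- tapply(profile$count, profile$orientation, sum)
  names(by_orient)[which.max(by_orient)]
}
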