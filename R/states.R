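#' Connectivity-state detection
#'
#' Re-occurring connectivity states are communities of time windows whose
#' graphs are mutually similar. Each window is reduced to its nodal
#' strength profile; the window x window Pearson correlation matrix of
#' these profiles (the CCS matrix) is treated as a weighted graph (negative
#' entries clipped to zero, diagonal removed) and partitioned by Newman's
#' leading-eigenvector modularity algorithm with Kernighan-Lin-style
#' refinement. The number of modules is the number of states; the windows
#' of each module are averaged (on R, then re-split by sign) into the
#' state graph.
#'
#' @name state_detection
NULL

#' Nodal-strength profiles of every window
#'
#' @param seq `dynamic_graph_seq`.
#' @param sign `"positive"` (W+) or `"negative"` (W-).
#' @return matrix windows x N of nodal strengths.
#' @export
strength_profiles <- function(seq, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(inherits(seq, "dynamic_graph_seq"), length(seq$starts) >= 1)
  wkey <- if (sign == "positive") "w_plus" else "w_minus"
  t(vapply(seq$signed, function(sp) nodal_strength(sp[[wkey]]),
           numeric(nrow(seq$r[[1]]))))
}

#' Window-similarity (CCS) matrix
#'
#' Pearson correlation between every pair of window strength profiles.
#'
#' @param profiles matrix windows x N from [strength_profiles()].
#' @return symmetric windows x windows matrix, unit diagonal.
#' @export
ccs_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need >= 2 windows, got ", nrow(profiles))
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant strength profile in window(s): ",
         paste(which(sds == 0) - 1L, collapse = ", "))
  }
  ccs <- stats::cor(t(profiles))
  ccs[lower.tri(ccs)] <- t(ccs)[lower.tri(ccs)]
  diag(ccs) <- 1
  ccs
}

# Gain from flipping vertex i given s and Bg: dQ_i = -4 s_i (Bg s - diag terms)
# Passes are capped: refinement is a polish step and each pass is monotone
# in the best configuration found, so a handful of passes suffices.
.kl_refine <- function(Bg, s, max_passes = 20L) {
  n <- length(s)
  dBg <- diag(Bg)
  for (pass in seq_len(max_passes)) {
    q0 <- drop(s %*% Bg %*% s)
    moved <- rep(FALSE, n)
    s_work <- s
    best_q <- q0
    best_s <- s
    q <- q0
    Bs <- drop(Bg %*% s_work)
    for (step in seq_len(n)) {
      gain <- -4 * s_work * (Bs - dBg * s_work)
      gain[moved] <- -Inf
      i <- which.max(gain)
      q <- q + gain[i]
      s_work[i] <- -s_work[i]
      Bs <- Bs + 2 * Bg[, i] * s_work[i]
      moved[i] <- TRUE
      if (q > best_q + 1e-12) {
        best_q <- q
        best_s <- s_work
      }
    }
    if (best_q > q0 + 1e-12) s <- best_s else break
  }
  s
}

#' Detect connectivity states by Newman modularity
#'
#' Negative CCS entries are clipped to 0 and the diagonal zeroed; the
#' resulting weighted graph is recursively bisected along the leading
#' eigenvector of the (generalized) modularity matrix, each split refined
#' by Kernighan-Lin-style single-vertex moves and accepted only if its
#' modularity contribution exceeds 1e-10. Deterministic: the eigenvector
#' sign is fixed so its largest-magnitude entry is positive. States are
#' relabelled by descending occupancy.
#'
#' @param ccs matrix from [ccs_matrix()].
#' @return list of class `state_partition`: `assignment` (state id per
#'   window, 1..K), `K`, `occupancy` (windows per state), `modularity`.
#' @export
detect_states <- function(ccs) {
  A <- as.matrix(ccs)
  stopifnot(nrow(A) == ncol(A))
  A[A < 0] <- 0
  diag(A) <- 0
  n <- nrow(A)
  if (all(A == 0)) {
    warning("CCS is all-zero after clipping negatives; single state")
    return(structure(list(assignment = rep(1L, n), K = 1L,
                          occupancy = n, modularity = 0),
                     class = "state_partition"))
  }
  k <- rowSums(A)
  m2 <- sum(k)                       # = 2m
  B <- A - outer(k, k) / m2
  assignment <- integer(n)
  next_id <- 1L
  groups <- list(seq_len(n))
  while (length(groups)) {
    g <- groups[[1]]
    groups <- groups[-1]
    if (length(g) == 1L) {
      assignment[g] <- next_id; next_id <- next_id + 1L
      next
    }
    Bg <- B[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    eig <- eigen(Bg, symmetric = TRUE)
    v <- eig$vectors[, 1]
    if (v[which.max(abs(v))] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    dq <- -Inf
    if (eig$values[1] > 1e-12 && length(unique(s)) == 2L) {
      s <- .kl_refine(Bg, s)
      dq <- drop(s %*% Bg %*% s) / (2 * m2)
    }
    if (!is.finite(dq) || dq <= 1e-10 || length(unique(s)) < 2L) {
      assignment[g] <- next_id; next_id <- next_id + 1L
    } else {
      groups <- c(groups, list(g[s > 0]), list(g[s < 0]))
    }
  }
  # relabel by descending occupancy, ties by first appearance
  occ <- table(assignment)
  ord <- order(-as.integer(occ), as.integer(names(occ)))
  relabel <- integer(length(occ))
  relabel[as.integer(names(occ))[ord]] <- seq_along(ord)
  assignment <- relabel[assignment]
  occ <- as.integer(table(assignment))
  Q <- .partition_modularity(A, assignment)
  structure(list(assignment = assignment, K = length(occ),
                 occupancy = occ, modularity = Q),
            class = "state_partition")
}

.partition_modularity <- function(A, assignment) {
  k <- rowSums(A)
  m2 <- sum(k)
  if (m2 == 0) return(0)
  same <- outer(assignment, assignment, "==")
  sum((A - outer(k, k) / m2)[same]) / m2
}

#' @export
print.state_partition <- function(x, ...) {
  cat("state partition: K = ", x$K, " states over ", length(x$assignment),
      " windows; occupancy ", paste(x$occupancy, collapse = "/"),
      "; Q = ", sprintf("%.4f", x$modularity), "\n", sep = "")
  invisible(x)
}

#' Average window graphs into state graphs
#'
#' Element-wise mean of the window correlation matrices within each state,
#' then a signed split of each mean.
#'
#' @param seq `dynamic_graph_seq`.
#' @param assignment state id per window (from [detect_states()]).
#' @return list, one element per state id, each with `r` (mean correlation
#'   graph), `signed` ([split_signed()] of the mean), `n_windows`.
#' @export
state_graphs <- function(seq, assignment) {
  stopifnot(inherits(seq, "dynamic_graph_seq"),
            length(assignment) == length(seq$starts))
  ids <- sort(unique(assignment))
  if (!all(seq_len(max(ids)) %in% ids)) {
    stop("empty state id(s): ",
         paste(setdiff(seq_len(max(ids)), ids), collapse = ", "))
  }
  lapply(ids, function(id) {
    members <- which(assignment == id)
    r_mean <- Reduce(`+`, seq$r[members]) / length(members)
    list(r = r_mean, signed = split_signed(r_mean),
         n_windows = length(members))
  })
}
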