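#' Group-level repeated-measures statistics
#'
#' One measure (a global metric, a nodal metric at one node, or a VAR/LFA
#' dynamic summary) is observed per subject in every band x condition
#' cell: a complete within-subject 5 x 2 design. Inference uses the
#' classical univariate repeated-measures ANOVA with sphericity assumed
#' (compound symmetry implies sphericity), post-hoc paired t-tests, and
#' Benjamini-Hochberg FDR control across nodes.
#'
#' @name group_stats
NULL

#' Two-way within-subject repeated-measures ANOVA
#'
#' Subject is the random factor; band and condition are within-subject
#' fixed factors. Each effect is tested against its own subject-by-effect
#' interaction stratum: F dfs are (b-1, (b-1)(n-1)) for band, (c-1,
#' (c-1)(n-1)) for condition and ((b-1)(c-1), (b-1)(c-1)(n-1)) for the
#' interaction.
#'
#' @param table numeric array subjects x bands x conditions (complete; no
#'   missing cells).
#' @return list with `F_band`, `p_band`, `F_cond`, `p_cond`, `F_inter`,
#'   `p_inter`, and `dfs` (named list of (num, den) pairs).
#' @export
rm_anova <- function(table) {
  stopifnot(length(dim(table)) == 3)
  if (anyNA(table)) stop("missing cells: the design must be complete")
  n <- dim(table)[1]; b <- dim(table)[2]; cc <- dim(table)[3]
  if (n < 3) stop("need >= 3 subjects, got ", n)
  d <- data.frame(
    y = as.vector(table),
    subject = factor(rep(seq_len(n), times = b * cc)),
    band = factor(rep(rep(seq_len(b), each = n), times = cc)),
    cond = factor(rep(seq_len(cc), each = n * b))
  )
  fit <- stats::aov(y ~ band * cond + Error(subject / (band * cond)),
                    data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  fb <- pull("Error: subject:band", "band")
  fc <- pull("Error: subject:cond", "cond")
  fi <- pull("Error: subject:band:cond", "band:cond")
  list(F_band = unname(fb["F"]), p_band = unname(fb["p"]),
       F_cond = unname(fc["F"]), p_cond = unname(fc["p"]),
       F_inter = unname(fi["F"]), p_inter = unname(fi["p"]),
       dfs = list(band = c(b - 1, (b - 1) * (n - 1)),
                  cond = c(cc - 1, (cc - 1) * (n - 1)),
                  inter = c((b - 1) * (cc - 1), (b - 1) * (cc - 1) * (n - 1))))
}

#' Two-sided paired t-test
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `df`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x - y) == 0) {
    stop("zero-variance differences: paired t is undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level `q`: reject all hypotheses whose BH-adjusted
#' p-value is at most `q`.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param q FDR level.
#' @return logical vector, TRUE where rejected.
#' @export
fdr_bh <- function(pvalues, q) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), q > 0, q < 1)
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Nodal condition tests with FDR control
#'
#' Runs [rm_anova()] per node, applies BH correction across nodes to the
#' condition-effect p-values, and for the surviving nodes runs post-hoc
#' paired t-tests (condition 2 vs condition 1) within each band.
#'
#' @param tables named list, one subjects x bands x conditions array per
#'   node; all arrays must share dimensions.
#' @param q FDR level (default 0.001).
#' @return list with `results` (data.frame: node, F_cond, p_cond, q_cond,
#'   significant), `significant_nodes` (character), and `posthoc`
#'   (data.frame node x band paired-t results for surviving nodes).
#' @export
nodal_condition_tests <- function(tables, q = 0.001) {
  stopifnot(length(tables) >= 1)
  dims <- lapply(tables, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("inconsistent subject/band/condition axes across nodes")
  }
  nodes <- names(tables)
  if (is.null(nodes)) nodes <- paste0("node", seq_along(tables))
  fits <- lapply(tables, rm_anova)
  p_cond <- vapply(fits, `[[`, numeric(1), "p_cond")
  q_cond <- stats::p.adjust(p_cond, method = "BH")
  sig <- q_cond <= q
  results <- data.frame(
    node = nodes,
    F_cond = vapply(fits, `[[`, numeric(1), "F_cond"),
    p_cond = p_cond, q_cond = q_cond, significant = sig,
    row.names = NULL
  )
  posthoc <- NULL
  if (any(sig)) {
    nb <- dim(tables[[1]])[2]
    rows <- list()
    for (nd in which(sig)) {
      for (band in seq_len(nb)) {
        pt <- paired_t(tables[[nd]][, band, 2], tables[[nd]][, band, 1])
        rows[[length(rows) + 1L]] <- data.frame(
          node = nodes[nd], band = band, t = pt$t, p = pt$p, df = pt$df)
      }
    }
    posthoc <- do.call(rbind, rows)
  }
  list(results = results, significant_nodes = nodes[sig], posthoc = posthoc)
}
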