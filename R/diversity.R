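#' Alpha diversity of one sample
#'
#' Observed richness, bias-corrected Chao1 and Shannon entropy (natural
#' log) from one sample's count vector. Chao1 uses the bias-corrected form
#' `S_obs + F1*(F1-1) / (2*(F2+1))` (F1 singletons, F2 doubletons), which
#' stays defined when no doubletons occur.
#'
#' @param counts non-negative integer vector, at least one positive entry.
#' @return List: `observed_richness`, `chao1`, `shannon` (nats).
#' @export
#' @examples
#' alpha_diversity(c(1, 1, 2, 5, 9)) # chao1 = 5.5
alpha_diversity <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero count vector has no diversity")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  p <- counts[counts > 0] / sum(counts)
  shannon <- -sum(p * log(p))
  list(observed_richness = s_obs, chao1 = chao1, shannon = shannon)
}

#' Alpha diversity for every sample of a count table
#'
#' @param ct a [count_table()] with no all-zero samples.
#' @param rarefy logical; subsample all samples to the minimum depth first
#'   (depth-evening is exposed as an option, off by default).
#' @param seed seed used when `rarefy = TRUE`.
#' @return Data frame: `sample_id`, `observed_richness`, `chao1`, `shannon`.
#' @export
alpha_diversity_table <- function(ct, rarefy = FALSE, seed = 1L) {
  check_no_empty_samples(ct)
  counts <- ct$counts
  if (isTRUE(rarefy)) {
    set.seed(seed)
    depth <- min(colSums(counts))
    counts <- apply(counts, 2, function(x) {
      picks <- sample(rep.int(seq_along(x), x), depth)
      tabulate(picks, nbins = length(x))
    })
  }
  res <- apply(counts, 2, alpha_diversity)
  data.frame(
    sample_id = ct$samples,
    observed_richness = vapply(res, `[[`, numeric(1), "observed_richness"),
    chao1 = vapply(res, `[[`, numeric(1), "chao1"),
    shannon = vapply(res, `[[`, numeric(1), "shannon"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Kruskal-Wallis with Dunn's post hoc letters
#'
#' Kruskal-Wallis test across groups, followed by Dunn's pairwise z tests on
#' the pooled ranks (with tie correction), Benjamini-Hochberg adjustment
#' over all pairs, and a compact-letter display: groups sharing a letter are
#' not significantly different at `alpha`. The letters are protected by the
#' omnibus test — when the Kruskal-Wallis p value exceeds `alpha`, all
#' groups share one letter (the classic protected post hoc procedure);
#' the pairwise table is always reported.
#'
#' @param values numeric vector of per-sample values.
#' @param groups group label per value; >= 2 groups with >= 2 observations
#'   each.
#' @param alpha significance level for the letters.
#' @return List: `kw` (the `stats::kruskal.test` result), `pairwise` (data
#'   frame: group pair, z, p, p_adj), `letters` (named character vector).
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(10), rnorm(10), rnorm(10, 8))
#' g <- rep(c("a", "b", "c"), each = 10)
#' kruskal_dunn(v, g)$letters
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) with < 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  kw <- stats::kruskal.test(values, factor(groups))

  n <- length(values)
  r <- rank(values)
  # tie correction for the Dunn variance
  tie <- table(values)
  tie_term <- sum(tie^3 - tie) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ng <- as.numeric(sizes[names(rbar)])
  names(ng) <- names(rbar)

  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / ng[pr[1]] + 1 / ng[pr[2]]))
    (rbar[pr[1]] - rbar[pr[2]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = "BH")
  pairwise <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = as.numeric(z), p = as.numeric(p), p_adj = as.numeric(p_adj),
    row.names = NULL, stringsAsFactors = FALSE
  )
  letters_out <- if (kw$p.value > alpha) {
    stats::setNames(rep("a", length(lev)), lev) # omnibus not significant
  } else {
    compact_letters(lev, pairwise, alpha, order_by = rbar[lev])
  }
  list(kw = kw, pairwise = pairwise, letters = letters_out)
}

# Compact-letter display: letters = maximal cliques of the graph whose
# edges connect pairs that are NOT significantly different.
compact_letters <- function(levels, pairwise, alpha, order_by = NULL) {
  k <- length(levels)
  adj <- matrix(TRUE, k, k, dimnames = list(levels, levels))
  sig <- pairwise$p_adj <= alpha
  for (i in which(sig)) {
    adj[pairwise$group1[i], pairwise$group2[i]] <- FALSE
    adj[pairwise$group2[i], pairwise$group1[i]] <- FALSE
  }
  cliques <- bron_kerbosch(adj)
  # stable letter order: cliques sorted by the best-ranked member
  if (!is.null(order_by)) {
    ord <- order(vapply(cliques, function(cl) min(rank(-order_by)[cl]),
                        numeric(1)))
    cliques <- cliques[ord]
  }
  out <- stats::setNames(rep("", k), levels)
  for (ci in seq_along(cliques)) {
    members <- levels[cliques[[ci]]]
    out[members] <- paste0(out[members], letters[ci])
  }
  out
}

# maximal cliques of a small undirected graph (adjacency with TRUE diagonal)
bron_kerbosch <- function(adj) {
  k <- nrow(adj)
  res <- list()
  recurse <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      res[[length(res) + 1]] <<- sort(R)
      return()
    }
    for (v in P) {
      nb <- which(adj[v, ] & seq_len(k) != v)
      recurse(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  recurse(integer(0), seq_len(k), integer(0))
  res
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)`, computed on relative
#' abundances by default (library sizes in this design vary roughly
#' ninefold) or on raw counts.
#'
#' @param ct a [count_table()] with no all-zero samples.
#' @param on_proportions normalize each sample to proportions first.
#' @return Symmetric numeric matrix with sample ids as dimnames, zero
#'   diagonal, entries in `[0, 1]`.
#' @export
bray_curtis <- function(ct, on_proportions = TRUE) {
  check_no_empty_samples(ct)
  x <- ct$counts
  if (isTRUE(on_proportions)) x <- sweep(x, 2, colSums(x), "/")
  num <- as.matrix(stats::dist(t(x), method = "manhattan"))
  cs <- colSums(x)
  den <- outer(cs, cs, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(ct$samples, ct$samples)
  d
}

#' PERMANOVA by permutation on a distance matrix
#'
#' Pseudo-F from the among/within decomposition of the Gower-centred
#' distance matrix; the p value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#' Optional `strata` restrict permutations to within-block exchanges
#' (e.g. plots nested in farms).
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups factor-like group label per sample (>= 2 levels, each with
#'   >= 2 samples).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param strata optional blocking label per sample.
#' @return List of class `"permanova_result"`: `factor_name`, `pseudo_F`,
#'   `p_value`, `n_permutations`, `R2`. The permutations used are attached
#'   as attribute `"permutations"` (one row per permutation).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L, strata = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("grouping factor needs >= 2 levels")
  if (any(sizes < 2)) stop("each group needs >= 2 samples")

  # Gower centring of -d^2/2
  a <- -0.5 * d^2
  G <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)

  X <- stats::model.matrix(~g, data.frame(g = factor(groups)))
  H <- X %*% solve(crossprod(X), t(X))
  a_lev <- length(sizes)
  ss_total <- sum(diag(G))
  ss_among <- sum(G * H) # tr(GH), both symmetric
  f_obs <- (ss_among / (a_lev - 1)) /
    ((ss_total - ss_among) / (n - a_lev))
  r2 <- ss_among / ss_total

  set.seed(seed)
  perms <- matrix(0L, n_perm, n)
  f_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- permute_within(n, strata)
    perms[b, ] <- p
    ssb <- sum(G[p, p] * H)
    f_perm[b] <- (ssb / (a_lev - 1)) / ((ss_total - ssb) / (n - a_lev))
  }
  p_value <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  out <- list(factor_name = deparse(substitute(groups)),
              pseudo_F = f_obs, p_value = p_value,
              n_permutations = n_perm, R2 = r2)
  class(out) <- "permanova_result"
  attr(out, "permutations") <- perms
  out
}

permute_within <- function(n, strata) {
  if (is.null(strata)) return(sample.int(n))
  p <- seq_len(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    p[idx] <- idx[sample.int(length(idx))]
  }
  p
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g, R2 = %.3f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$R2, x$p_value, x$n_permutations
  ))
  invisible(x)
}

#' Principal coordinates and constrained ordination (CAP)
#'
#' Unconstrained: classical PCoA by eigen-decomposition of the
#' Gower-centred matrix; negative eigenvalues are dropped (their summed
#' magnitude is recorded in the result, no correction applied).
#' Constrained (distance-based RDA flavour of CAP): the retained PCoA axes
#' are projected onto the constraint space by least squares, and the
#' constrained axes are the singular vectors of the fitted values.
#'
#' @param d symmetric dissimilarity matrix.
#' @param constraints optional data frame of constraining variables (rows
#'   aligned with the samples). `NULL` or zero columns gives plain PCoA.
#' @return List of class `"ordination_result"`: `scores` (samples x axes),
#'   `eigenvalues` (non-increasing), `constrained`, `prop_explained`,
#'   `negative_eigen_mass`, `rank_warning`.
#' @export
cap_ordination <- function(d, constraints = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  G <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-8
  keep <- eg$values > tol
  neg_mass <- sum(abs(eg$values[eg$values < -tol]))
  if (neg_mass > 0) {
    message(sprintf(
      "dropping negative PCoA eigenvalues (total magnitude %.3g)", neg_mass
    ))
  }
  lam <- eg$values[keep]
  scores <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), sum(keep))
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("Axis", seq_len(ncol(scores)))
  total_inertia <- sum(lam)

  rank_warning <- FALSE
  if (!is.null(constraints) && NCOL(constraints) > 0) {
    cdf <- as.data.frame(constraints)
    if (nrow(cdf) != n) stop("constraint rows must align with samples")
    X <- stats::model.matrix(~., cdf)[, -1, drop = FALSE]
    X <- scale(X, center = TRUE, scale = FALSE)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning("rank-deficient constraints; using ", qx$rank, " of ",
              ncol(X), " columns")
      rank_warning <- TRUE
    }
    fitted_scores <- qr.fitted(qx, scores)
    sv <- svd(fitted_scores)
    keep_c <- sv$d^2 > tol
    n_axes <- min(sum(keep_c), qx$rank)
    ax <- seq_len(n_axes)
    cap_scores <- sv$u[, ax, drop = FALSE] %*% diag(sv$d[ax], n_axes)
    rownames(cap_scores) <- rownames(d)
    colnames(cap_scores) <- paste0("CAP", ax)
    eigvals <- sv$d[ax]^2
    out <- list(scores = cap_scores, eigenvalues = eigvals,
                constrained = TRUE,
                prop_explained = eigvals / total_inertia,
                negative_eigen_mass = neg_mass,
                rank_warning = rank_warning)
  } else {
    out <- list(scores = scores, eigenvalues = lam, constrained = FALSE,
                prop_explained = lam / total_inertia,
                negative_eigen_mass = neg_mass,
                rank_warning = rank_warning)
  }
  class(out) <- "ordination_result"
  out
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf(
    "%s ordination: %d axes; axis 1 explains %.1f%% of inertia\n",
    if (x$constrained) "Constrained (CAP)" else "PCoA",
    length(x$eigenvalues), 100 * x$prop_explained[1]
  ))
  invisible(x)
}
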