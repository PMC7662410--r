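# Partial least squares path modeling (PLS-PM), implemented from scratch:
# reflective (Mode A) measurement model, iterative outer-weight estimation
# with selectable inner weighting scheme, structural coefficients by
# ordinary least squares on latent scores, goodness-of-fit, bootstrap
# significance and permutation-based multigroup comparison.

#' Path model specification
#'
#' @param blocks named list: latent variable name -> character vector of
#'   manifest variable (column) names. All blocks are reflective (Mode A).
#' @param paths data.frame with columns `from`, `to` giving the directed
#'   structural edges; the implied graph must be acyclic.
#' @return a `path_model_spec` object with `blocks`, `paths` and a logical
#'   adjacency matrix `adjacency` (`adjacency[i, j]` is TRUE when latent
#'   variable `j` is a predecessor of latent variable `i`).
#' @export
path_model_spec <- function(blocks, paths) {
  lvs <- names(blocks)
  if (is.null(lvs) || any(!nzchar(lvs))) {
    stop_anspm("blocks must be a named list", class = "anspm_invalid_argument")
  }
  mvs <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(mvs)) {
    stop_anspm("every manifest variable must belong to exactly one block",
               class = "anspm_invalid_argument")
  }
  if (!is.data.frame(paths) || !all(c("from", "to") %in% names(paths))) {
    stop_anspm("paths needs columns from, to", class = "anspm_invalid_argument")
  }
  bad <- setdiff(c(paths$from, paths$to), lvs)
  if (length(bad)) {
    stop_anspm("unknown latent variable in paths: ", paste(bad, collapse = ", "),
               class = "anspm_invalid_argument")
  }
  adj <- matrix(FALSE, length(lvs), length(lvs), dimnames = list(lvs, lvs))
  for (k in seq_len(nrow(paths))) adj[paths$to[k], paths$from[k]] <- TRUE
  spec <- structure(list(blocks = blocks, paths = paths, adjacency = adj),
                    class = "path_model_spec")
  validate_path_model(spec)
  spec
}

validate_path_model <- function(spec) {
  stopifnot(inherits(spec, "path_model_spec"))
  # acyclicity: repeatedly strip nodes without predecessors
  adj <- spec$adjacency
  remaining <- rownames(adj)
  while (length(remaining)) {
    src <- remaining[rowSums(adj[remaining, remaining, drop = FALSE]) == 0]
    if (!length(src)) {
      stop_anspm("structural model contains a cycle", class = "anspm_cyclic_model")
    }
    remaining <- setdiff(remaining, src)
  }
  invisible(spec)
}

#' Default four-construct ANS/recall path model
#'
#' Blocks: Sympathetic `{lf, sdnn, ns_scr, mean_scl}`, Vagal
#' `{hf, pnn50, rmssd}`, ANS `{lf_hf, avnn}`, Recall `{recall_score}`;
#' structural edges Sympathetic -> ANS, Vagal -> ANS, ANS -> Recall.
#'
#' @return a [path_model_spec()].
#' @export
default_path_model <- function() {
  path_model_spec(
    blocks = list(
      Sympathetic = c("lf", "sdnn", "ns_scr", "mean_scl"),
      Vagal = c("hf", "pnn50", "rmssd"),
      ANS = c("lf_hf", "avnn"),
      Recall = "recall_score"
    ),
    paths = data.frame(from = c("Sympathetic", "Vagal", "ANS"),
                       to = c("ANS", "ANS", "Recall"),
                       stringsAsFactors = FALSE)
  )
}

#' Align manifest-variable signs within each block
#'
#' Reflective blocks require all indicators of a construct to point the
#' same way; physiological indices do not (e.g. vagal tone raises some
#' HRV indices and lowers others). Within each multi-indicator block, an
#' indicator is negated when its correlation with the block's first
#' principal component is negative. The component is oriented so the
#' block's first indicator keeps its sign, making the flip set
#' deterministic. Single-indicator blocks are untouched.
#'
#' @param table indicator data.frame containing all manifest variables.
#' @param spec a [path_model_spec()].
#' @return list: `table` (sign-adjusted copy) and `flipped` (character
#'   vector of negated column names).
#' @export
align_indicator_signs <- function(table, spec = default_path_model()) {
  validate_path_model(spec)
  flipped <- character(0)
  for (lv in names(spec$blocks)) {
    mvs <- spec$blocks[[lv]]
    X <- as.matrix(table[, mvs, drop = FALSE])
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0 | is.na(sds))) {
      stop_anspm("zero-variance manifest variable in block ", lv, ": ",
                 paste(mvs[sds == 0 | is.na(sds)], collapse = ", "),
                 class = "anspm_zero_variance")
    }
    if (length(mvs) < 2L) next
    Z <- scale(X)
    pc1 <- eigen(stats::cor(X), symmetric = TRUE)$vectors[, 1L]
    score <- Z %*% pc1
    r <- as.numeric(stats::cor(Z, score))
    # orient the component with the first indicator (fall back to majority)
    orient <- if (abs(r[1L]) > 1e-12) sign(r[1L]) else sign(sum(r) + 1e-300)
    r <- r * orient
    neg <- mvs[r < 0]
    for (mv in neg) table[[mv]] <- -table[[mv]]
    flipped <- c(flipped, neg)
  }
  list(table = table, flipped = flipped)
}

# ---------------------------------------------------------------------------
# Core iterative estimation (lean matrix engine shared by fit/bootstrap/perm)

# Sign alignment on a plain matrix: same rule as align_indicator_signs but
# without data.frame overhead; returns the column sign vector.
align_signs_matrix <- function(X, block_idx) {
  s <- rep(1, ncol(X))
  for (ix in block_idx) {
    if (length(ix) < 2L) next
    C <- stats::cor(X[, ix, drop = FALSE])
    if (anyNA(C)) stop_anspm("zero-variance manifest variable",
                             class = "anspm_zero_variance")
    pc1 <- eigen(C, symmetric = TRUE)$vectors[, 1L]
    r <- as.numeric(C %*% pc1)  # proportional to cor(MV, PC score)
    orient <- if (abs(r[1L]) > 1e-12) sign(r[1L]) else sign(sum(r) + 1e-300)
    s[ix] <- ifelse(r * orient < 0, -1, 1)
  }
  s
}

# Structural OLS on unit-variance latent scores; returns betas in the order
# of the (to, from) pairs listed in `edges` (a two-column integer matrix).
engine_betas <- function(Y, adj, edges) {
  n <- nrow(Y)
  beta <- numeric(nrow(edges))
  for (lv in unique(edges[, 1L])) {
    pred <- which(adj[lv, ])
    Yp <- Y[, pred, drop = FALSE]
    G <- crossprod(Yp) / (n - 1L)
    coefs <- tryCatch(solve(G, crossprod(Yp, Y[, lv]) / (n - 1L)),
                      error = function(e) stop_anspm(
                        "singular predictor matrix", class = "anspm_singular"))
    for (k in seq_along(pred)) {
      beta[edges[, 1L] == lv & edges[, 2L] == pred[k]] <- coefs[k]
    }
  }
  beta
}

# Fast path used by resampling loops: X is the raw indicator matrix (rows
# already subset), returns the structural coefficient vector only.
plspm_beta_fast <- function(X, block_idx, adj, edges, scheme, tol, max_iter) {
  s <- align_signs_matrix(X, block_idx)
  if (any(s < 0)) X <- sweep(X, 2L, s, "*")
  eng <- plspm_engine(X, block_idx, adj, scheme, tol, max_iter)
  engine_betas(eng$Y, adj, edges)
}

# Precompute the index structures the fast path needs from a spec.
spec_index <- function(spec, mvs) {
  lvs <- names(spec$blocks)
  edges <- cbind(match(spec$paths$to, lvs), match(spec$paths$from, lvs))
  list(block_idx = lapply(spec$blocks, function(b) match(b, mvs)),
       adj = spec$adjacency, edges = edges)
}

standardize_cols <- function(X) {
  mu <- colMeans(X)
  X <- sweep(X, 2L, mu, "-")
  sds <- sqrt(colSums(X^2) / (nrow(X) - 1L))
  if (any(sds == 0 | !is.finite(sds))) {
    stop_anspm("zero-variance manifest variable",
               class = "anspm_zero_variance")
  }
  sweep(X, 2L, sds, "/")
}

plspm_engine <- function(X, block_idx, adj, scheme, tol, max_iter) {
  n <- nrow(X)
  L <- length(block_idx)
  connected <- adj | t(adj)
  Xs <- standardize_cols(X)
  # scores of the (unnormalized) weight list plus the scale factors that
  # make each score unit-variance; Xs columns are centered so scores are too
  compute_scores <- function(w) {
    Y <- matrix(0, n, L)
    for (b in seq_len(L)) {
      Y[, b] <- Xs[, block_idx[[b]], drop = FALSE] %*% w[[b]]
    }
    sds <- sqrt(colSums(Y^2) / (n - 1L))
    if (any(!is.finite(sds) | sds == 0)) {
      stop_anspm("degenerate outer weights", class = "anspm_singular")
    }
    list(Y = Y * rep(1 / sds, each = n), sds = sds)
  }
  w <- lapply(block_idx, function(ix) rep(1, length(ix)))
  cs <- compute_scores(w)
  w <- mapply(function(wb, s) wb / s, w, cs$sds, SIMPLIFY = FALSE)
  Y <- cs$Y
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    R <- crossprod(Y) / (n - 1L)  # scores are standardized: this is cor(Y)
    E <- matrix(0, L, L)
    for (b in seq_len(L)) {
      nb <- which(connected[b, ])
      if (!length(nb)) next
      if (scheme == "centroid") {
        E[b, nb] <- sign(R[b, nb])
      } else if (scheme == "factorial") {
        E[b, nb] <- R[b, nb]
      } else {  # path scheme
        pred <- which(adj[b, ])
        succ <- setdiff(nb, pred)
        if (length(pred)) {
          G <- R[pred, pred, drop = FALSE]
          coefs <- tryCatch(solve(G, R[pred, b]),
                            error = function(e) stop_anspm(
                              "singular predictor matrix in inner estimation",
                              class = "anspm_singular"))
          E[b, pred] <- coefs
        }
        if (length(succ)) E[b, succ] <- R[b, succ]
      }
    }
    Z <- Y %*% t(E)
    w_raw <- vector("list", L)
    for (b in seq_len(L)) {
      z <- Z[, b]
      if (all(z == 0)) z <- Y[, b]  # isolated LV: keep its own score
      # Mode A: weight proportional to cov(indicator, inner estimate)
      w_raw[[b]] <- as.numeric(crossprod(Xs[, block_idx[[b]], drop = FALSE], z))
    }
    cs <- compute_scores(w_raw)
    w_new <- mapply(function(wb, s) wb / s, w_raw, cs$sds, SIMPLIFY = FALSE)
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    Y <- cs$Y
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # deterministic orientation: each LV positively correlated with the first
  # indicator of its block
  for (b in seq_len(L)) {
    r1 <- sum(Y[, b] * Xs[, block_idx[[b]][1L]])
    if (is.finite(r1) && r1 < 0) {
      Y[, b] <- -Y[, b]
      w[[b]] <- -w[[b]]
    }
  }
  list(Xs = Xs, Y = Y, w = w, n_iterations = iter, converged = converged)
}

#' Fit a PLS path model with reflective indicators
#'
#' Manifest variables are standardized; outer weights are iterated in
#' Mode A (weight proportional to the correlation of the indicator with
#' the inner estimate of its construct) under the chosen inner weighting
#' scheme until the largest outer-weight change falls below `tol`.
#' Latent scores are the weighted sums of standardized indicators,
#' re-standardized to unit variance. Structural path coefficients are
#' ordinary-least-squares coefficients of each endogenous construct's
#' score on its predecessors' scores; with standardized scores these are
#' the standardized betas of the structural regressions.
#'
#' Rows containing missing indicator values are dropped (the count is kept
#' in the fit). Non-convergence within `max_iter` produces a warning and a
#' fit flagged `converged = FALSE`.
#'
#' @param table indicator data.frame (one row per observation).
#' @param spec a [path_model_spec()] (default [default_path_model()]).
#' @param scheme inner weighting scheme: `"path"` (default), `"centroid"`
#'   or `"factorial"`.
#' @param tol convergence tolerance on the maximum absolute outer-weight
#'   change (default 1e-7).
#' @param max_iter maximum outer iterations (default 300).
#' @param align if TRUE (default) run [align_indicator_signs()] first.
#' @return a `plspm_fit` object: `outer_weights`, `loadings`,
#'   `communality` (all named by manifest variable), `lv_scores` matrix,
#'   `paths` data.frame (`from`, `to`, `beta`), `r_squared` (named by
#'   endogenous construct), `gof`, `n_iterations`, `converged`,
#'   `n_dropped`, `flipped`.
#' @examples
#' truth <- latent_ground_truth(loadings = 0.9,
#'                              path_coefficients = c(0.6, -0.5, 0.4),
#'                              noise_sd = 0.3, n_subjects = 200, seed = 7)
#' tab <- generate_indicator_table(truth)
#' fit <- fit_plspm(tab)
#' fit$paths
#' @export
fit_plspm <- function(table, spec = default_path_model(),
                      scheme = c("path", "centroid", "factorial"),
                      tol = 1e-7, max_iter = 300L, align = TRUE) {
  scheme <- match.arg(scheme)
  validate_path_model(spec)
  mvs <- unlist(spec$blocks, use.names = FALSE)
  missing_cols <- setdiff(mvs, names(table))
  if (length(missing_cols)) {
    stop_anspm("table is missing columns: ", paste(missing_cols, collapse = ", "),
               class = "anspm_invalid_argument")
  }
  X <- as.matrix(table[, mvs, drop = FALSE])
  ok <- stats::complete.cases(X)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  adj <- spec$adjacency
  max_pred <- max(rowSums(adj))
  if (nrow(X) < max_pred + 2L) {
    stop_anspm("too few rows to fit the structural regressions",
               class = "anspm_invalid_argument")
  }
  flipped <- character(0)
  if (align) {
    al <- align_indicator_signs(as.data.frame(X), spec)
    X <- as.matrix(al$table[, mvs, drop = FALSE])
    flipped <- al$flipped
  }
  lvs <- names(spec$blocks)
  block_idx <- lapply(spec$blocks, function(b) match(b, mvs))
  eng <- plspm_engine(X, block_idx, adj, scheme, tol, max_iter)
  if (!eng$converged) {
    warning("PLS-PM did not converge within ", max_iter, " iterations")
  }
  Y <- eng$Y
  colnames(Y) <- lvs
  loadings <- stats::setNames(numeric(length(mvs)), mvs)
  for (b in seq_along(lvs)) {
    ix <- block_idx[[b]]
    loadings[ix] <- as.numeric(stats::cor(eng$Xs[, ix, drop = FALSE], Y[, b]))
  }
  endo <- lvs[rowSums(adj) > 0]
  betas <- numeric(0)
  paths <- spec$paths
  paths$beta <- NA_real_
  r_squared <- stats::setNames(numeric(length(endo)), endo)
  n <- nrow(Y)
  for (lv in endo) {
    pred <- lvs[adj[lv, ]]
    Yp <- Y[, pred, drop = FALSE]
    G <- crossprod(Yp) / (n - 1L)
    coefs <- tryCatch(solve(G, crossprod(Yp, Y[, lv]) / (n - 1L)),
                      error = function(e) stop_anspm(
                        "singular predictor matrix for ", lv,
                        class = "anspm_singular"))
    fitted <- Yp %*% coefs
    rss <- sum((Y[, lv] - fitted)^2)
    tss <- sum(Y[, lv]^2)  # scores are centered, unit variance
    r_squared[lv] <- 1 - rss / tss
    for (k in seq_along(pred)) {
      paths$beta[paths$to == lv & paths$from == pred[k]] <- coefs[k]
    }
  }
  communality <- loadings^2
  gof <- sqrt(mean(communality) * mean(r_squared))
  w_vec <- numeric(length(mvs))
  w_vec[unlist(block_idx)] <- unlist(eng$w)
  structure(list(
    outer_weights = stats::setNames(w_vec, mvs),
    loadings = loadings,
    communality = communality,
    lv_scores = Y,
    paths = paths,
    r_squared = r_squared,
    gof = gof,
    n_iterations = eng$n_iterations,
    converged = eng$converged,
    n_dropped = n_dropped,
    n_used = n,
    flipped = flipped,
    scheme = scheme,
    spec = spec
  ), class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("<plspm_fit> %d rows, scheme '%s', %s in %d iterations\n",
              x$n_used, x$scheme,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat("Path coefficients:\n")
  print(x$paths, row.names = FALSE)
  cat(sprintf("R^2: %s\n", paste(sprintf("%s = %.3f", names(x$r_squared),
                                         x$r_squared), collapse = ", ")))
  cat(sprintf("GoF: %.3f\n", x$gof))
  invisible(x)
}

#' Goodness-of-fit of a PLS path model
#'
#' `GoF = sqrt(mean(communality) * mean(R^2))`: the geometric mean of the
#' average indicator communality (over all manifest variables) and the
#' average R-squared over endogenous constructs.
#'
#' @param fit a `plspm_fit`.
#' @return the scalar GoF in `[0, 1]`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "plspm_fit"))
  if (!fit$converged) {
    stop_anspm("fit did not converge; GoF undefined", class = "anspm_not_converged")
  }
  if (length(fit$r_squared) == 0L) {
    stop_anspm("model has no endogenous construct", class = "anspm_invalid_argument")
  }
  sqrt(mean(fit$communality) * mean(fit$r_squared))
}

#' Bootstrap significance of path coefficients
#'
#' Rows are resampled with replacement; each resample is sign-aligned and
#' refitted. A path is flagged significant at level `alpha` when the
#' two-sided percentile confidence interval of its coefficient excludes
#' zero. Resamples that produce a zero-variance indicator or a singular
#' structural regression are redrawn (the count is reported).
#'
#' @inheritParams fit_plspm
#' @param n_boot number of bootstrap resamples (>= 100; default 500).
#' @param seed integer seed.
#' @param alpha two-sided significance level (default 0.05).
#' @return data.frame with one row per structural edge: `from`, `to`,
#'   `beta` (original-fit coefficient), `se`, `ci_lo`, `ci_hi`,
#'   `significant`, `p_normal` (normal-approximation p-value); attributes
#'   `n_boot`, `n_redrawn`, `alpha`.
#' @export
bootstrap_paths <- function(table, spec = default_path_model(),
                            n_boot = 500L, seed = 1L, alpha = 0.05,
                            scheme = "path", tol = 1e-7, max_iter = 300L) {
  if (n_boot < 100L) {
    stop_anspm("n_boot must be >= 100", class = "anspm_invalid_argument")
  }
  fit0 <- fit_plspm(table, spec, scheme = scheme, tol = tol, max_iter = max_iter)
  mvs <- unlist(spec$blocks, use.names = FALSE)
  X <- as.matrix(table[, mvs, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  si <- spec_index(spec, mvs)
  n <- nrow(X)
  n_edges <- nrow(fit0$paths)
  B <- matrix(NA_real_, n_boot, n_edges)
  n_redrawn <- 0L
  with_seed(derive_seed(seed, 101L), {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      beta <- tryCatch(
        plspm_beta_fast(X[idx, , drop = FALSE], si$block_idx, si$adj,
                        si$edges, scheme, tol, max_iter),
        anspm_error = function(e) NULL)
      if (is.null(beta)) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 10L * n_boot) {
          stop_anspm("bootstrap keeps producing degenerate resamples",
                     class = "anspm_singular")
        }
        next
      }
      B[b, ] <- beta
      b <- b + 1L
    }
  })
  lo <- apply(B, 2, stats::quantile, probs = alpha / 2)
  hi <- apply(B, 2, stats::quantile, probs = 1 - alpha / 2)
  se <- apply(B, 2, stats::sd)
  beta <- fit0$paths$beta
  out <- data.frame(
    from = fit0$paths$from, to = fit0$paths$to,
    beta = beta, se = se, ci_lo = lo, ci_hi = hi,
    significant = (lo > 0) | (hi < 0),
    p_normal = 2 * stats::pnorm(-abs(beta) / pmax(se, .Machine$double.eps)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "alpha") <- alpha
  out
}

#' Permutation test for group differences in path coefficients
#'
#' The observed statistic per structural edge is the difference of the
#' coefficients from independent group-wise fits. Its null distribution
#' is built by refitting both groups under random permutations of the
#' group labels; the p-value is
#' `(1 + #{|perm diff| >= |observed diff|}) / (1 + n_perm)`.
#'
#' @inheritParams fit_plspm
#' @param group vector with exactly two levels, one entry per row of
#'   `table`; each group needs at least 3 rows.
#' @param n_perm number of label permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return a `group_comparison` object: data.frame `edges` (`from`, `to`,
#'   `beta_a`, `beta_b`, `diff`, `p_value`), plus `groups`, `n_perm`, `seed`.
#' @export
permutation_group_test <- function(table, spec = default_path_model(),
                                   group, n_perm = 999L, seed = 1L,
                                   scheme = "path", tol = 1e-7,
                                   max_iter = 300L) {
  if (n_perm < 99L) {
    stop_anspm("n_perm must be >= 99", class = "anspm_invalid_argument")
  }
  group <- as.factor(group)
  if (nlevels(group) != 2L || length(group) != nrow(table)) {
    stop_anspm("group must have exactly 2 levels and one entry per row",
               class = "anspm_invalid_argument")
  }
  if (any(table(group) < 3L)) {
    stop_anspm("each group needs at least 3 rows", class = "anspm_invalid_argument")
  }
  validate_path_model(spec)
  mvs <- unlist(spec$blocks, use.names = FALSE)
  X <- as.matrix(table[, mvs, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  group <- group[ok]
  si <- spec_index(spec, mvs)
  is_a <- group == levels(group)[1L]
  fit_groups <- function(ga) {
    beta_a <- plspm_beta_fast(X[ga, , drop = FALSE], si$block_idx, si$adj,
                              si$edges, scheme, tol, max_iter)
    beta_b <- plspm_beta_fast(X[!ga, , drop = FALSE], si$block_idx, si$adj,
                              si$edges, scheme, tol, max_iter)
    list(a = beta_a, b = beta_b)
  }
  obs_fit <- fit_groups(is_a)
  obs <- obs_fit$a - obs_fit$b
  n_edges <- length(obs)
  exceed <- integer(n_edges)
  with_seed(derive_seed(seed, 202L), {
    for (p in seq_len(n_perm)) {
      gp <- sample(is_a)
      d <- tryCatch({f <- fit_groups(gp); f$a - f$b},
                    anspm_error = function(e) rep(Inf, n_edges))
      exceed <- exceed + (abs(d) >= abs(obs))
    }
  })
  edges <- data.frame(
    from = spec$paths$from, to = spec$paths$to,
    beta_a = obs_fit$a, beta_b = obs_fit$b,
    diff = obs, p_value = (1 + exceed) / (1 + n_perm),
    stringsAsFactors = FALSE
  )
  structure(list(edges = edges, groups = levels(group),
                 n_perm = n_perm, seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s, %d permutations\n",
              x$groups[1], x$groups[2], x$n_perm))
  print(x$edges, row.names = FALSE)
  invisible(x)
}
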