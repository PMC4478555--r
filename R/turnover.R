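## Two-state continuous-time Markov model of element gain and loss on a
## phylogeny. States are 0 (absent) and 1 (present); branch lengths are
## expected nucleotide substitutions per site, so rates are expressed as
## gains/losses per site per nucleotide substitution.

#' Transition probabilities of the two-state gain/loss process
#'
#' For gain rate \eqn{\alpha} (0 to 1) and loss rate \eqn{\beta} (1 to 0),
#' the transition probability matrix over time \eqn{t} is
#' \deqn{P(t) = \frac{1}{\alpha+\beta}
#'   \begin{pmatrix} \beta + \alpha e^{-(\alpha+\beta)t} &
#'                   \alpha (1 - e^{-(\alpha+\beta)t}) \\
#'                   \beta (1 - e^{-(\alpha+\beta)t}) &
#'                   \alpha + \beta e^{-(\alpha+\beta)t} \end{pmatrix}}
#' with rows indexed by the starting state (0, 1).
#'
#' @param gain Gain rate \eqn{\alpha \ge 0}.
#' @param loss Loss rate \eqn{\beta \ge 0}.
#' @param t Elapsed time (branch length), \eqn{t \ge 0}.
#' @return A 2x2 row-stochastic matrix with dimnames `c("0","1")`.
#' @examples
#' gl_transition_matrix(1, 1, log(2) / 2)  # P01 = 0.25
#' @export
gl_transition_matrix <- function(gain, loss, t) {
  stopifnot(gain >= 0, loss >= 0, t >= 0)
  if (gain == 0 && loss == 0) {
    warning("gain and loss both 0; returning identity")
    return(matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("0", "1"), c("0", "1"))))
  }
  s <- gain + loss
  e <- exp(-s * t)
  matrix(c((loss + gain * e) / s, gain * (1 - e) / s,
           loss * (1 - e) / s, (gain + loss * e) / s),
         2, 2, byrow = TRUE, dimnames = list(c("0", "1"), c("0", "1")))
}

root_prior_vector <- function(root_prior, gain, loss) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 1L, root_prior >= 0, root_prior <= 1)
    return(c(1 - root_prior, root_prior))
  }
  switch(match.arg(root_prior, c("stationary", "uniform")),
         stationary = c(loss, gain) / (gain + loss),
         uniform = c(0.5, 0.5))
}

## normalise a presence/absence matrix argument: positions x strains,
## integer 0/1/NA, strains matched to (a subset of) tree tips
check_pa_matrix <- function(mat, tree) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  if (is.character(mat)) {
    out <- suppressWarnings(matrix(as.integer(mat), nrow(mat), ncol(mat),
                                   dimnames = dimnames(mat)))
    out[mat == "?"] <- NA
    mat <- out
  }
  storage.mode(mat) <- "integer"
  if (any(!(mat %in% c(0L, 1L)) & !is.na(mat)))
    stop("presence/absence matrix cells must be 0, 1 or NA/'?'")
  missing_tips <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing_tips))
    stop("strain(s) not in tree: ", paste(missing_tips, collapse = ", "))
  if (any(rowSums(!is.na(mat)) == 0L))
    stop("matrix contains all-missing row(s)")
  mat
}

## Collapse identical tip-state patterns; returns list(patterns, weights,
## index) where patterns is a pattern x strains matrix.
compress_patterns <- function(mat) {
  key <- apply(mat, 1L, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(patterns = mat[first, , drop = FALSE],
       weights = as.vector(table(idx)[as.character(seq_len(sum(first)))]),
       index = idx)
}

## Felsenstein pruning, vectorised over site patterns. Returns list with
## per-node partial likelihood matrices (2 x npat), per-edge child
## contributions P %*% L_child, log scale factors, and the tree in
## postorder. States matrix must already be patterns x tips.
prune_partials <- function(tree, patterns, gain, loss) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- nrow(patterns)
  patterns <- patterns[, tree$tip.label, drop = FALSE]
  L <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    s <- patterns[, i]
    L[[i]] <- rbind(as.numeric(is.na(s) | s == 0L),
                    as.numeric(is.na(s) | s == 1L))
  }
  edge <- tree$edge
  contrib <- vector("list", nrow(edge))
  logscale <- numeric(npat)
  last_edge_of_parent <- tapply(seq_len(nrow(edge)), edge[, 1L], max)
  for (k in seq_len(nrow(edge))) {
    pa <- edge[k, 1L]; ch <- edge[k, 2L]
    P <- gl_transition_matrix(gain, loss, tree$edge.length[k])
    contrib[[k]] <- P %*% L[[ch]]
    L[[pa]] <- if (is.null(L[[pa]])) contrib[[k]] else L[[pa]] * contrib[[k]]
    if (k == last_edge_of_parent[[as.character(pa)]]) {
      mx <- pmax(L[[pa]][1L, ], L[[pa]][2L, ])
      mx[mx == 0] <- 1
      L[[pa]] <- sweep(L[[pa]], 2L, mx, "/")
      logscale <- logscale + log(mx)
    }
  }
  list(tree = tree, L = L, contrib = contrib, logscale = logscale,
       ntip = ntip, root = ntip + 1L)
}

#' Log-likelihood of a presence/absence matrix under the gain/loss model
#'
#' Felsenstein pruning over homologous positions. Missing cells (`NA` or
#' `"?"`) contribute an uninformative partial likelihood of (1, 1) rather
#' than dropping the position.
#'
#' @param tree An [ape::phylo] tree with branch lengths in substitutions
#'   per site; tips must cover all matrix strains (extra tips are pruned).
#' @param mat Presence/absence matrix, positions x strains, values
#'   0/1/NA (or characters `"0"`, `"1"`, `"?"`).
#' @param gain,loss Non-negative rates.
#' @param root_prior `"stationary"` (default), `"uniform"`, or a single
#'   number giving the prior probability of state present at the root.
#' @return Log-likelihood in nats.
#' @export
turnover_loglik <- function(tree, mat, gain, loss, root_prior = "stationary") {
  tree <- validate_tree(tree)
  mat <- check_pa_matrix(mat, tree)
  if (length(tree$tip.label) > ncol(mat))
    tree <- ape::keep.tip(tree, colnames(mat))
  cp <- compress_patterns(mat)
  pr <- prune_partials(tree, cp$patterns, gain, loss)
  prior <- root_prior_vector(root_prior, gain, loss)
  site_ll <- log(colSums(prior * pr$L[[pr$root]])) + pr$logscale
  sum(site_ll * cp$weights)
}

#' Fit the gain/loss model by maximum likelihood
#'
#' Fits the two-state continuous-time Markov model of element presence and
#' absence on a phylogeny, either with a single rate (\eqn{\alpha=\beta=\mu},
#' `"one_rate"`) or with separate gain and loss rates (`"two_rate"`).
#' Optimisation is on the log-rate scale; the two-rate fit uses several
#' deterministic starting points, always including the one-rate optimum so
#' that the two-rate log-likelihood can never fall below the one-rate one.
#' Standard errors come from the inverse numerical observed-information
#' matrix (central differences on the log scale, delta-method transform).
#'
#' @inheritParams turnover_loglik
#' @param model `"two_rate"` or `"one_rate"`.
#' @param rate_bounds Search bounds for rates (per substitution).
#' @return An object of class `"turnover_fit"` with components
#'   `model`, `rates` (named vector: `gain`, `loss` — equal under
#'   `one_rate`), `se`, `logLik`, `npar`, `vcov_log` (covariance of log
#'   rates), `boundary` (logical), `root_prior`, `tree`, `data`,
#'   `n_positions`, `convergence`.
#' @seealso [likelihood_ratio_test()], [ancestral_posteriors()],
#'   [simulate.turnover_fit()]
#' @examples
#' tr <- ape::rphylo(8, 1, 0)
#' tr$edge.length <- tr$edge.length / sum(tr$edge.length)
#' m <- simulate_pa_matrix(tr, 50, gain = 2, loss = 3, seed = 1)
#' fit <- fit_turnover(tr, m, model = "two_rate")
#' coef(fit)
#' @export
fit_turnover <- function(tree, mat, model = c("two_rate", "one_rate"),
                         root_prior = "stationary",
                         rate_bounds = c(1e-6, 1e6)) {
  model <- match.arg(model)
  tree <- validate_tree(tree)
  mat <- check_pa_matrix(mat, tree)
  if (length(tree$tip.label) > ncol(mat))
    tree <- ape::keep.tip(tree, colnames(mat))
  cp <- compress_patterns(mat)
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])

  nll1 <- function(lmu) {
    mu <- exp(lmu)
    -sum(cp$weights * site_loglik(tree, cp$patterns, mu, mu, root_prior))
  }
  nll2 <- function(p) {
    -sum(cp$weights * site_loglik(tree, cp$patterns, exp(p[1L]), exp(p[2L]),
                                  root_prior))
  }

  ## one-rate optimum is also the anchor start for the two-rate search
  o1 <- optimise(nll1, c(lb, ub), tol = 1e-10)
  lmu <- o1$minimum

  if (model == "one_rate") {
    par <- c(lmu, lmu)
    value <- o1$objective
    npar <- 1L
    H <- num_hessian(function(x) nll1(x[1L]), lmu)
    vcov_log <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 1, 1))
    se_log <- safe_sqrt(diag(vcov_log))
    se <- c(gain = exp(lmu) * se_log, loss = exp(lmu) * se_log)
    conv <- 0L
  } else {
    starts <- list(c(lmu, lmu), c(0, 0), c(3, 3),
                   c(lmu - 1.5, lmu + 1.5), c(lmu + 1.5, lmu - 1.5))
    best <- NULL
    conv <- 0L
    for (st in starts) {
      st <- pmin(pmax(st, lb + 1e-9), ub - 1e-9)
      o <- tryCatch(
        optim(st, nll2, method = "L-BFGS-B", lower = lb, upper = ub,
              control = list(factr = 1e5)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("two-rate optimisation failed from all starts")
    if (best$value > o1$objective + 1e-8) {
      ## should not happen (one-rate optimum is a start); keep the better
      best <- list(par = c(lmu, lmu), value = o1$objective, convergence = 1L)
    }
    par <- best$par
    value <- best$value
    npar <- 2L
    conv <- best$convergence
    H <- num_hessian(nll2, par)
    vcov_log <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
    se <- exp(par) * safe_sqrt(diag(vcov_log))
    names(se) <- c("gain", "loss")
  }

  rates <- c(gain = exp(par[1L]), loss = exp(par[2L]))
  row_states <- rowSums(mat == 1L, na.rm = TRUE)
  row_n <- rowSums(!is.na(mat))
  uninformative <- all(row_states == row_n) || all(row_states == 0L)
  boundary <- uninformative ||
    any(par <= lb + 1e-6) || any(par >= ub - 1e-6)
  if (boundary) se[] <- NA_real_
  if (any(!is.finite(se))) se[!is.finite(se)] <- NA_real_

  structure(list(model = model, rates = rates, se = se,
                 logLik = -value, npar = npar, vcov_log = vcov_log,
                 boundary = boundary, root_prior = root_prior,
                 tree = tree, data = mat, n_positions = nrow(mat),
                 convergence = conv),
            class = "turnover_fit")
}

## per-pattern log-likelihood vector (used by the optimiser)
site_loglik <- function(tree, patterns, gain, loss, root_prior) {
  pr <- prune_partials(tree, patterns, gain, loss)
  prior <- root_prior_vector(root_prior, gain, loss)
  log(colSums(prior * pr$L[[pr$root]])) + pr$logscale
}

## sqrt that maps a negative (non-positive-definite information) or
## missing variance to NA instead of warning
safe_sqrt <- function(x) ifelse(is.na(x) | x < 0, NA_real_, sqrt(pmax(x, 0)))

num_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- ej <- numeric(n); ei[i] <- h; ej[j] <- h
    if (i == j) {
      H[i, i] <- (f(x + ei) - 2 * f(x) + f(x - ei)) / h^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat(sprintf("Gain/loss turnover fit (%s model)\n", x$model))
  cat(sprintf("  positions: %d, strains: %d\n",
              x$n_positions, ncol(x$data)))
  if (x$model == "one_rate") {
    cat(sprintf("  rate (mu): %.4g", x$rates[["gain"]]))
    if (!is.na(x$se[["gain"]])) cat(sprintf(" +/- %.3g", x$se[["gain"]]))
    cat("\n")
  } else {
    cat(sprintf("  gain: %.4g", x$rates[["gain"]]))
    if (!is.na(x$se[["gain"]])) cat(sprintf(" +/- %.3g", x$se[["gain"]]))
    cat(sprintf("\n  loss: %.4g", x$rates[["loss"]]))
    if (!is.na(x$se[["loss"]])) cat(sprintf(" +/- %.3g", x$se[["loss"]]))
    cat("\n")
  }
  cat(sprintf("  log-likelihood: %.4f\n", x$logLik))
  if (x$boundary)
    cat("  note: boundary/uninformative fit; standard errors unavailable\n")
  invisible(x)
}

#' @method coef turnover_fit
#' @export
coef.turnover_fit <- function(object, ...) {
  if (object$model == "one_rate") c(mu = unname(object$rates[["gain"]]))
  else object$rates
}

#' @method logLik turnover_fit
#' @export
logLik.turnover_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n_positions,
            class = "logLik")
}

#' @method vcov turnover_fit
#' @export
vcov.turnover_fit <- function(object, ...) {
  ## delta-method covariance on the natural rate scale
  r <- if (object$model == "one_rate") object$rates[["gain"]] else object$rates
  J <- diag(r, nrow = object$npar)
  V <- J %*% object$vcov_log %*% J
  nm <- if (object$model == "one_rate") "mu" else c("gain", "loss")
  dimnames(V) <- list(nm, nm)
  V
}

#' @method summary turnover_fit
#' @export
summary.turnover_fit <- function(object, ...) {
  est <- coef(object)
  se <- if (object$model == "one_rate") object$se[["gain"]] else object$se
  tab <- cbind(Estimate = est, `Std. Error` = unname(se))
  structure(list(fit = object, coefficients = tab),
            class = "summary.turnover_fit")
}

#' @export
print.summary.turnover_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (per site per nucleotide substitution):\n")
  print(x$coefficients)
  invisible(x)
}

#' Likelihood-ratio test of equal gain and loss rates
#'
#' Compares the one-rate (null) and two-rate (alternative) fits on the same
#' data and tree: statistic \eqn{2\Delta\ln L}, referred to a chi-square
#' distribution with 1 degree of freedom.
#'
#' @param fit_one A one-rate [fit_turnover()] object.
#' @param fit_two A two-rate fit of the same matrix and tree.
#' @param tolerance Small negative statistics within this tolerance are
#'   clamped to 0; larger negative values are an optimiser-failure error.
#' @return An object of class `"turnover_lrt"`: list with `statistic`,
#'   `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_one, fit_two, tolerance = 1e-6) {
  stopifnot(inherits(fit_one, "turnover_fit"), inherits(fit_two, "turnover_fit"))
  if (fit_one$model != "one_rate" || fit_two$model != "two_rate")
    stop("arguments must be a one-rate fit and a two-rate fit, in that order")
  if (fit_one$n_positions != fit_two$n_positions ||
      !identical(dim(fit_one$data), dim(fit_two$data)))
    stop("fits are not on the same data")
  stat <- 2 * (fit_two$logLik - fit_one$logLik)
  if (stat < -tolerance)
    stop("negative likelihood-ratio statistic (", format(stat),
         "): optimiser failure")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1L, lower.tail = FALSE)),
            class = "turnover_lrt")
}

#' @export
print.turnover_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test, gain = loss (df = %d)\n", x$df))
  cat(sprintf("  2*dlnL = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' @export
anova.turnover_fit <- function(object, object2, ...) {
  fits <- list(object, object2)
  models <- vapply(fits, `[[`, "", "model")
  one <- fits[[match("one_rate", models)]]
  two <- fits[[match("two_rate", models)]]
  if (is.null(one) || is.null(two))
    stop("anova needs one one-rate and one two-rate fit")
  likelihood_ratio_test(one, two)
}

#' Marginal ancestral-state posteriors
#'
#' Posterior probability of state "present" at the root (and optionally at
#' every internal node) for each homologous position, computed by the
#' standard two-pass (inside/outside) algorithm with the fit's rates and
#' root prior.
#'
#' @param fit A converged [fit_turnover()] object.
#' @param nodes `"root"` or `"all"` (all internal nodes).
#' @return A matrix, positions x nodes, of posterior probabilities of
#'   presence. Column names are `"root"` and, for `"all"`, the internal
#'   ape node numbers (`"node<k>"`).
#' @export
ancestral_posteriors <- function(fit, nodes = c("root", "all")) {
  nodes <- match.arg(nodes)
  tree <- fit$tree
  mat <- fit$data
  gain <- fit$rates[["gain"]]; loss <- fit$rates[["loss"]]
  cp <- compress_patterns(mat)
  pr <- prune_partials(tree, cp$patterns, gain, loss)
  prior <- root_prior_vector(fit$root_prior, gain, loss)
  tree <- pr$tree
  npat <- nrow(cp$patterns)
  ntip <- pr$ntip
  nnode <- ntip + tree$Nnode

  ## outside pass (preorder = reverse postorder edge sweep)
  O <- vector("list", nnode)
  O[[pr$root]] <- matrix(prior, 2L, npat)
  edge <- tree$edge
  children_of <- split(seq_len(nrow(edge)), edge[, 1L])
  for (k in rev(seq_len(nrow(edge)))) {
    pa <- edge[k, 1L]; ch <- edge[k, 2L]
    if (ch <= ntip && nodes == "root") next
    sibs <- setdiff(children_of[[as.character(pa)]], k)
    acc <- O[[pa]]
    for (s in sibs) acc <- acc * pr$contrib[[s]]
    P <- gl_transition_matrix(gain, loss, tree$edge.length[k])
    O[[ch]] <- crossprod(P, acc)
  }

  post_node <- function(v) {
    joint <- O[[v]] * pr$L[[v]]
    joint[2L, ] / colSums(joint)
  }
  wanted <- if (nodes == "root") pr$root else (ntip + 1L):nnode
  post <- vapply(wanted, post_node, numeric(npat))
  post <- matrix(post, nrow = npat)
  colnames(post) <- ifelse(wanted == pr$root, "root", paste0("node", wanted))
  out <- post[cp$index, , drop = FALSE]
  rownames(out) <- rownames(mat)
  out
}

#' Simulate presence/absence matrices from a fitted turnover model
#'
#' @param object A [fit_turnover()] object.
#' @param nsim Number of replicate matrices.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` presence/absence matrices with the same
#'   dimensions as the fitted data.
#' @export
simulate.turnover_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_pa_matrix(object$tree, object$n_positions,
                       gain = object$rates[["gain"]],
                       loss = object$rates[["loss"]],
                       root_prior = object$root_prior))
}

#' Pairwise presence/absence difference
#'
#' Proportion of differing states between two strain profiles,
#' \eqn{\#different / (\#identical + \#different)}, computed over the sites
#' where both profiles are non-missing.
#'
#' @param profile_a,profile_b Equal-length vectors over \{0, 1, NA\} (or
#'   characters `"0"`, `"1"`, `"?"`).
#' @return The difference fraction. Error if no shared informative site.
#' @export
pairwise_difference <- function(profile_a, profile_b) {
  norm <- function(p) {
    if (is.character(p)) { p[p == "?"] <- NA; p <- as.integer(p) }
    p
  }
  a <- norm(profile_a); b <- norm(profile_b)
  if (length(a) != length(b)) stop("profiles differ in length")
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no shared informative site")
  mean(a[keep] != b[keep])
}
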