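state_codes <- c(generalist = 0L, specialist = 1L)

check_state_tree <- function(tree, states) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape::phylo tree.")
  if (!ape::is.rooted(tree)) abort("Tree must be rooted.")
  if (is.null(names(states))) {
    if (length(states) != ape::Ntip(tree)) {
      abort("Unnamed `states` must match the number of tips.")
    }
    names(states) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss) > 0) {
    abort(paste0("Tips without a state: ", paste(miss, collapse = ", ")))
  }
  st <- states[tree$tip.label]
  if (is.character(st) || is.factor(st)) {
    st <- state_codes[as.character(st)]
    if (anyNA(st)) abort("States must be 'generalist' or 'specialist'.")
  }
  if (!all(st %in% c(0, 1))) abort("States must be coded 0/1.")
  as.integer(st)
}

#' BiSSE log-likelihood
#'
#' Likelihood of a rooted tree and binary tip states under the binary-state
#' speciation-extinction model: the coupled extinction/data differential
#' equations are integrated from the tips to the root along every branch
#' (adaptive Runge-Kutta with per-branch renormalisation against underflow);
#' at internal nodes the per-state data variables combine as
#' `lambda_k * D_left * D_right`, and at the root the two state likelihoods
#' are combined according to `root`.
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths.
#' @param states Tip states: named vector of `"generalist"`/`"specialist"`
#'   (or 0/1), or unnamed in tip order.
#' @param pars Named rates `lambda_g`, `lambda_s`, `mu_g`, `mu_s`, `q_gs`,
#'   `q_sg` (all >= 0).
#' @param root Root-state treatment: `"weighted"` (weights proportional to
#'   each state's conditional likelihood at the root; default), `"equal"`,
#'   or `"given"` (supply `root_p`).
#' @param root_p Root state probabilities for `root = "given"`.
#' @param condition_survival Condition the likelihood on survival of both
#'   root lineages (off by default).
#' @param tol Absolute/relative ODE tolerance.
#' @return Log-likelihood (may be `-Inf` for impossible parameters).
#' @export
bisse_loglik <- function(tree, states, pars, root = c("weighted", "equal",
                                                      "given"),
                         root_p = c(0.5, 0.5), condition_survival = FALSE,
                         tol = 1e-8) {
  root <- match.arg(root)
  st <- check_state_tree(tree, states)
  need <- c("lambda_g", "lambda_s", "mu_g", "mu_s", "q_gs", "q_sg")
  if (!all(need %in% names(pars))) {
    abort(paste("`pars` must be named:", paste(need, collapse = ", ")))
  }
  pars <- as.numeric(pars[need])
  if (any(pars < 0) || any(!is.finite(pars))) {
    abort("All rates must be finite and >= 0.")
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ll <- bisse_loglik_cpp(tr$edge, tr$edge.length, ape::Ntip(tr), st, pars,
                         match(root, c("weighted", "equal", "given")) - 1L,
                         root_p, condition_survival, tol)
  if (is.nan(ll)) abort("Non-finite BiSSE likelihood.")
  ll
}

#' Two-step maximum-likelihood BiSSE fit
#'
#' Step 1 fits the constrained model in which generalists and specialists
#' share speciation and extinction rates and the transition rate is
#' symmetric (3 free parameters), starting from character-independent
#' birth-death heuristics. Step 2 releases all six rates and maximises the
#' likelihood by Nelder-Mead in log-rate space from the constrained optimum
#' plus jittered restarts. The two nested fits are compared with a
#' chi-squared likelihood-ratio test (df = 3), and the diversification
#' potential `DP = lambda + t_in - mu` of each state is reported, `t_in`
#' being the transition rate into the focal state (the DPs using the
#' outgoing rate are also included).
#'
#' @inheritParams bisse_loglik
#' @param n_starts Number of optimisation starts for the full model (the
#'   first is the constrained optimum; the rest are jittered).
#' @param seed RNG seed for the jittered restarts.
#' @return An object of class `bisse_fit` with the six rates, the two
#'   log-likelihoods, the likelihood-ratio test, and DP statistics; see
#'   [tidy.bisse_fit()] / [glance.bisse_fit()].
#' @export
bisse_fit <- function(tree, states, root = "weighted",
                      condition_survival = FALSE, n_starts = 3, seed = 1,
                      tol = 1e-8) {
  st <- check_state_tree(tree, states)
  if (ape::Ntip(tree) < 3) abort("Need at least 3 tips.")
  if (length(unique(st)) < 2) abort("Both states must be present at the tips.")

  mk_pars <- function(v) stats::setNames(v, c("lambda_g", "lambda_s", "mu_g",
                                              "mu_s", "q_gs", "q_sg"))
  ll_fun <- function(pars) {
    val <- try(bisse_loglik(tree, states, mk_pars(pars), root = root,
                            condition_survival = condition_survival,
                            tol = tol), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) -1e10 else val
  }

  # character-independent starting values: Yule-type speciation estimate
  la0 <- max((ape::Ntip(tree) - 2) / sum(tree$edge.length), 1e-4)
  start_c <- log(c(lambda = la0, mu = la0 / 10, q = la0 / 10))

  neg_c <- function(lp) -ll_fun(exp(lp)[c(1, 1, 2, 2, 3, 3)])
  opt_c <- stats::optim(start_c, neg_c, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
  ll_c <- -opt_c$value
  if (!is.finite(ll_c) || ll_c <= -1e9) {
    abort("Constrained BiSSE fit failed to find a finite likelihood.")
  }

  neg_f <- function(lp) -ll_fun(exp(lp))
  start_f <- opt_c$par[c(1, 1, 2, 2, 3, 3)]
  starts <- with_stream(seed, "bisse_fit", {
    c(list(start_f),
      purrr::map(seq_len(max(0, n_starts - 1)), function(i) {
        start_f + stats::rnorm(6, 0, 0.5)
      }))
  })
  fits <- purrr::map(starts, function(s) {
    stats::optim(s, neg_f, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-10))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  ll_f <- -best$value
  if (ll_f < ll_c) {  # nesting guarantee; NM from the constrained optimum
    ll_f <- ll_c      # cannot do worse than its own start
    best$par <- start_f
  }
  rates <- mk_pars(exp(best$par))

  chi2 <- max(0, 2 * (ll_f - ll_c))
  df <- 3
  pval <- stats::pchisq(chi2, df, lower.tail = FALSE)

  dp_g <- diversification_potential(rates[["lambda_g"]], rates[["q_sg"]],
                                    rates[["mu_g"]])
  dp_s <- diversification_potential(rates[["lambda_s"]], rates[["q_gs"]],
                                    rates[["mu_s"]])
  structure(list(
    rates = rates,
    constrained = mk_pars(exp(opt_c$par)[c(1, 1, 2, 2, 3, 3)]),
    loglik_full = ll_f, loglik_constrained = ll_c,
    chi2_stat = chi2, chi2_df = df, chi2_p = pval,
    dp_g = dp_g, dp_s = dp_s,
    dp_g_out = diversification_potential(rates[["lambda_g"]],
                                         rates[["q_gs"]], rates[["mu_g"]]),
    dp_s_out = diversification_potential(rates[["lambda_s"]],
                                         rates[["q_sg"]], rates[["mu_s"]]),
    dp_ratio = if (dp_g == 0) NA_real_ else dp_s / dp_g,
    n_tips = ape::Ntip(tree),
    root = root
  ), class = "bisse_fit")
}

#' @export
print.bisse_fit <- function(x, ...) {
  cat("<bisse_fit>", x$n_tips, "tips\n")
  cat(sprintf("  lambda_g %.4g  lambda_s %.4g  mu_g %.4g  mu_s %.4g\n",
              x$rates["lambda_g"], x$rates["lambda_s"], x$rates["mu_g"],
              x$rates["mu_s"]))
  cat(sprintf("  q_gs %.4g  q_sg %.4g\n", x$rates["q_gs"], x$rates["q_sg"]))
  cat(sprintf("  logLik full %.3f vs constrained %.3f; chi2(%d) = %.3f, p = %.3g\n",
              x$loglik_full, x$loglik_constrained, x$chi2_df, x$chi2_stat,
              x$chi2_p))
  cat(sprintf("  DP_g %.4g  DP_s %.4g  DP_s/DP_g %.4g\n",
              x$dp_g, x$dp_s, x$dp_ratio))
  invisible(x)
}

#' @rdname bisse_fit
#' @param x A `bisse_fit`.
#' @param ... Unused.
#' @method tidy bisse_fit
#' @export
tidy.bisse_fit <- function(x, ...) {
  tibble(term = names(x$rates),
         estimate = unname(x$rates),
         constrained = unname(x$constrained))
}

#' @rdname bisse_fit
#' @method glance bisse_fit
#' @export
glance.bisse_fit <- function(x, ...) {
  tibble(loglik_full = x$loglik_full,
         loglik_constrained = x$loglik_constrained,
         chi2_stat = x$chi2_stat, chi2_df = x$chi2_df, chi2_p = x$chi2_p,
         dp_g = x$dp_g, dp_s = x$dp_s, dp_ratio = x$dp_ratio,
         n_tips = x$n_tips)
}

#' Diversification potential
#'
#' `DP = lambda + t - mu`: a state's capacity to generate diversity, with
#' speciation and incoming transitions counting positively and extinction
#' negatively.
#'
#' @param lam,t_in,mu Speciation rate, transition rate into the focal state,
#'   and extinction rate (all >= 0).
#' @return Numeric DP (can be negative).
#' @export
diversification_potential <- function(lam, t_in, mu) {
  if (any(c(lam, t_in, mu) < 0)) abort("Rates must be >= 0.")
  lam + t_in - mu
}

#' @rdname diversification_potential
#' @param dp_s,dp_g Diversification potentials of specialists and
#'   generalists; `dp_g` must be non-zero.
#' @export
dp_ratio <- function(dp_s, dp_g) {
  if (any(dp_g == 0)) abort("dp_ratio undefined: dp_g is zero.")
  dp_s / dp_g
}

#' Root-to-tip path lengths
#'
#' Sum of branch lengths from the root to every tip, optionally labelled
#' with tip states.
#'
#' @param tree Rooted `ape::phylo` tree.
#' @param states Optional named tip states.
#' @return Tibble `tip`, `distance` (+ `state`).
#' @export
root_to_tip_lengths <- function(tree, states = NULL) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape::phylo tree.")
  if (!ape::is.rooted(tree)) abort("Tree must be rooted.")
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  out <- tibble(tip = tree$tip.label, distance = d)
  if (!is.null(states)) out$state <- unname(states[out$tip])
  out
}

#' Compare root-to-tip lengths between generalists and specialists
#'
#' Per-state median root-to-tip path length with a Wilcoxon rank-sum test.
#'
#' @inheritParams root_to_tip_lengths
#' @param states Named tip states (`"generalist"`/`"specialist"`).
#' @return One-row tibble: medians per state and the rank-sum p-value.
#' @export
root_to_tip_compare <- function(tree, states) {
  d <- root_to_tip_lengths(tree, states)
  if (length(setdiff(unique(d$state), c("generalist", "specialist"))) > 0) {
    abort("States must be generalist/specialist.")
  }
  g <- d$distance[d$state == "generalist"]
  s <- d$distance[d$state == "specialist"]
  if (length(g) == 0 || length(s) == 0) abort("Both states must be present.")
  wt <- stats::wilcox.test(s, g, exact = FALSE)
  tibble(median_generalist = stats::median(g),
         median_specialist = stats::median(s),
         p_value = wt$p.value)
}
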