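#' Design of a synthetic multi-habitat survey
#'
#' Describes the simulated sampling campaign and community structure used to
#' generate test data with known niche labels. The default design emulates a
#' 90-sample urban-park style survey: 5 habitats sampled in 6 parks with 3
#' replicates each, rarefaction-scale depth of 10,000 reads per sample, and a
#' community of 600 taxa of which 10% are planted habitat generalists (very
#' even habitat preferences), 30% planted specialists (single-habitat
#' preferences) and the rest background taxa of intermediate niche breadth.
#'
#' Habitat preference vectors are symmetric Dirichlet draws whose
#' concentration parameter is the single knob mapping to niche breadth: large
#' concentrations give even preferences (generalists), small ones give
#' one-hot preferences (specialists). Parks sit on a fixed 2-D unit grid and
#' every taxon is anchored to one park, with abundance attenuated by
#' `exp(-spatial_decay * distance)`; the decay can differ by niche class
#' (generalists are near-ubiquitous across parks, specialists strongly
#' spatially structured, mirroring the lower spatial turnover of generalists
#' seen in multi-habitat surveys). Baseline taxon abundances are lognormal;
#' generalists receive a mean-abundance multiplier because ubiquity at
#' adequate depth is what makes a generalist detectable at all.
#'
#' @param n_taxa Number of taxa.
#' @param habitats Character vector of habitat labels.
#' @param n_parks Number of parks; each park contains every habitat.
#' @param replicates Replicates per habitat x park cell.
#' @param depth Reads per sample (multinomial total).
#' @param generalist_frac,specialist_frac Proportions of planted generalists
#'   and specialists; the remainder are background taxa.
#' @param conc_generalist,conc_specialist,conc_background Symmetric Dirichlet
#'   concentrations of habitat preferences per class (all > 0).
#' @param spatial_decay Per-distance abundance attenuation (>= 0): a single
#'   value, or a named vector with entries `generalist`, `specialist`,
#'   `background`.
#' @param abundance_sdlog Lognormal sd of baseline taxon abundances.
#' @param generalist_abundance_mult Mean-abundance multiplier of generalists.
#' @param overdispersion Optional extra compositional noise: each sample's
#'   taxon probabilities are resampled from a Dirichlet with concentration
#'   `p / overdispersion` before multinomial sampling (0 = none).
#' @param seed Master RNG seed for the generator.
#'
#' @return A list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_taxa = 600,
                             habitats = c("moss", "sediment", "soil",
                                          "tree_hole", "water"),
                             n_parks = 6,
                             replicates = 3,
                             depth = 10000,
                             generalist_frac = 0.1,
                             specialist_frac = 0.3,
                             conc_generalist = 50,
                             conc_specialist = 0.05,
                             conc_background = 1,
                             spatial_decay = c(generalist = 0.2,
                                               specialist = 2.5,
                                               background = 0.8),
                             abundance_sdlog = 1.2,
                             generalist_abundance_mult = 8,
                             overdispersion = 0,
                             seed = 1) {
  assert_count(n_taxa, "n_taxa")
  assert_count(n_parks, "n_parks")
  assert_count(replicates, "replicates")
  if (!is.numeric(depth) || depth <= 0) abort("`depth` must be positive.")
  assert_prob(generalist_frac, "generalist_frac")
  assert_prob(specialist_frac, "specialist_frac")
  if (generalist_frac + specialist_frac > 1) {
    abort("generalist_frac + specialist_frac must not exceed 1.")
  }
  for (cc in c(conc_generalist, conc_specialist, conc_background)) {
    if (!is.numeric(cc) || cc <= 0) abort("Concentrations must be > 0.")
  }
  if (any(spatial_decay < 0)) abort("`spatial_decay` must be >= 0.")
  if (length(spatial_decay) == 1L) {
    spatial_decay <- c(generalist = unname(spatial_decay),
                       specialist = unname(spatial_decay),
                       background = unname(spatial_decay))
  }
  if (!all(c("generalist", "specialist", "background") %in%
             names(spatial_decay))) {
    abort("`spatial_decay` must be scalar or named generalist/specialist/background.")
  }
  structure(list(
    n_taxa = as.integer(n_taxa), habitats = habitats,
    n_parks = as.integer(n_parks), replicates = as.integer(replicates),
    depth = as.integer(depth),
    generalist_frac = generalist_frac, specialist_frac = specialist_frac,
    conc_generalist = conc_generalist, conc_specialist = conc_specialist,
    conc_background = conc_background,
    spatial_decay = spatial_decay[c("generalist", "specialist", "background")],
    abundance_sdlog = abundance_sdlog,
    generalist_abundance_mult = generalist_abundance_mult,
    overdispersion = overdispersion,
    seed = seed
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_design> %d taxa, %d habitats x %d parks x ",
                     "%d reps (%d samples), depth %d\n"),
              x$n_taxa, length(x$habitats), x$n_parks, x$replicates,
              length(x$habitats) * x$n_parks * x$replicates, x$depth))
  invisible(x)
}

# Fixed 2-D unit-spacing grid for parks; distances are Euclidean.
park_grid <- function(n_parks) {
  ncol <- ceiling(sqrt(n_parks))
  idx <- seq_len(n_parks) - 1L
  tibble(park = paste0("park", seq_len(n_parks)),
         x = idx %% ncol, y = idx %/% ncol)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) <= 0) {          # numerically degenerate at tiny concentrations:
    x[sample.int(length(alpha), 1L)] <- 1   # collapse to a single habitat
  }
  x / sum(x)
}

#' Generate a habitat-structured community with known niche labels
#'
#' Draws one count column per sample by multinomial sampling of taxon
#' relative intensities `abundance * habitat preference * park attenuation`,
#' so every column sums exactly to the design depth. Identical seeds give
#' identical outputs.
#'
#' @param design A [synthetic_design()].
#'
#' @return A list with elements `table` (a [community_table()]) and `truth`
#'   (tibble: taxon, planted label, anchor park, baseline abundance, and the
#'   habitat preference simplex in `pref_<habitat>` columns).
#' @export
generate_community <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  with_stream(d$seed, "community", {
    n_hab <- length(d$habitats)
    parks <- park_grid(d$n_parks)
    pdist <- as.matrix(stats::dist(parks[, c("x", "y")]))

    meta <- tidyr::expand_grid(park = parks$park, habitat = d$habitats,
                               rep = seq_len(d$replicates)) |>
      left_join(parks, by = "park") |>
      mutate(sample = sprintf("%s_%s_r%d", .data$habitat, .data$park,
                              .data$rep)) |>
      select("sample", "habitat", "park", "x", "y")

    n_gen <- round(d$generalist_frac * d$n_taxa)
    n_spc <- round(d$specialist_frac * d$n_taxa)
    label <- c(rep("generalist", n_gen), rep("specialist", n_spc),
               rep("background", d$n_taxa - n_gen - n_spc))
    conc <- c(generalist = d$conc_generalist, specialist = d$conc_specialist,
              background = d$conc_background)[label]
    decay <- d$spatial_decay[label]

    pref <- t(vapply(conc, function(a) rdirichlet1(rep(a, n_hab)),
                     numeric(n_hab)))
    colnames(pref) <- d$habitats
    abund <- stats::rlnorm(d$n_taxa, 0, d$abundance_sdlog) *
      ifelse(label == "generalist", d$generalist_abundance_mult, 1)
    anchor <- sample.int(d$n_parks, d$n_taxa, replace = TRUE)

    taxa <- sprintf("zotu%0*d", nchar(d$n_taxa), seq_len(d$n_taxa))
    counts <- matrix(0L, d$n_taxa, nrow(meta),
                     dimnames = list(taxa, meta$sample))
    park_idx <- match(meta$park, parks$park)
    for (j in seq_len(nrow(meta))) {
      p <- abund * pref[, meta$habitat[j]] *
        exp(-decay * pdist[cbind(anchor, park_idx[j])])
      if (d$overdispersion > 0) {
        p <- stats::rgamma(length(p), shape = p / d$overdispersion)
      }
      if (sum(p) <= 0) p[] <- 1
      counts[, j] <- stats::rmultinom(1L, d$depth, p)[, 1L]
    }

    truth <- tibble(taxon = taxa, label = label,
                    anchor_park = parks$park[anchor],
                    abundance = abund)
    truth <- dplyr::bind_cols(
      truth,
      as_tibble(`colnames<-`(pref, paste0("pref_", d$habitats)))
    )
    list(table = community_table(counts, meta), truth = truth)
  })
}

# -- tree simulators ---------------------------------------------------------

# Gillespie birth-death engine shared by generate_bd_tree() and
# simulate_bisse(). States are 1/2; rates are per-state. Stops when the
# extant count first reaches n_tips and then advances by one further
# exponential sojourn so terminal branches are strictly positive.
simulate_tree_engine <- function(n_tips, lambda, mu, q, root_state) {
  parent <- integer(0); btime <- numeric(0); state <- integer(0)
  dtime <- numeric(0); alive <- logical(0)
  new_lineage <- function(p, t, s) {
    parent[length(parent) + 1L] <<- p
    btime[length(btime) + 1L] <<- t
    state[length(state) + 1L] <<- s
    dtime[length(dtime) + 1L] <<- NA_real_
    alive[length(alive) + 1L] <<- TRUE
    length(parent)
  }
  new_lineage(0L, 0, root_state)
  t <- 0
  repeat {
    live <- which(alive)
    n_live <- length(live)
    if (n_live == 0L) return(NULL)
    rates_per <- lambda[state[live]] + mu[state[live]] + q[state[live]]
    total <- sum(rates_per)
    wait <- if (total > 0) stats::rexp(1L, total) else Inf
    if (n_live == n_tips) {
      t <- t + if (is.finite(wait)) wait else 1
      break
    }
    if (!is.finite(wait)) return(NULL)  # absorbed below target size
    t <- t + wait
    i <- live[sample.int(n_live, 1L, prob = rates_per)]
    s <- state[i]
    u <- stats::runif(1L) * (lambda[s] + mu[s] + q[s])
    if (u < lambda[s]) {
      alive[i] <- FALSE; dtime[i] <- t
      new_lineage(i, t, s); new_lineage(i, t, s)
    } else if (u < lambda[s] + mu[s]) {
      alive[i] <- FALSE; dtime[i] <- t
    } else {
      state[i] <- if (s == 1L) 2L else 1L
    }
  }
  dtime[alive] <- t
  list(parent = parent, btime = btime, dtime = dtime, alive = alive,
       state = state, present = t)
}

# Prune extinct lineages and emit Newick (tips labelled t1..tn in record
# order). Returns NULL if fewer than 2 extant tips survive.
engine_to_newick <- function(sim) {
  kids <- split(seq_along(sim$parent), sim$parent)
  tip_no <- 0L
  tip_states <- integer(0)
  build <- function(i) {
    ch <- kids[[as.character(i)]]
    if (is.null(ch)) {                       # leaf record
      if (!sim$alive[i]) return(NULL)
      tip_no <<- tip_no + 1L
      tip_states[tip_no] <<- sim$state[i]
      return(list(str = paste0("t", tip_no), len = sim$dtime[i] - sim$btime[i]))
    }
    sub <- Filter(Negate(is.null), lapply(ch, build))
    len <- sim$dtime[i] - sim$btime[i]
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L) {                 # collapse single-descendant node
      return(list(str = sub[[1L]]$str, len = sub[[1L]]$len + len))
    }
    list(str = paste0("(", sub[[1L]]$str, ":", format(sub[[1L]]$len, digits = 15),
                      ",", sub[[2L]]$str, ":", format(sub[[2L]]$len, digits = 15),
                      ")"),
         len = len)
  }
  root <- build(1L)
  if (is.null(root) || tip_no < 2L) return(NULL)
  list(newick = paste0(root$str, ";"), states = tip_states)
}

#' Simulate a birth-death tree conditioned on tip count
#'
#' Forward Gillespie simulation retried until `n_tips` extant lineages are
#' reached; extinct lineages are pruned so the returned tree is the
#' reconstructed (ultrametric) tree of the survivors.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Speciation and extinction rates; `birth > death >= 0`.
#' @param seed RNG seed.
#' @param max_tries Retry cap when the clade dies out before reaching
#'   `n_tips`.
#' @return An `ape::phylo` tree with `n_tips` tips.
#' @export
generate_bd_tree <- function(n_tips, birth, death = 0, seed = 1,
                             max_tries = 100) {
  assert_count(n_tips, "n_tips", min = 2)
  if (!(birth > death && death >= 0)) abort("Need birth > death >= 0.")
  with_stream(seed, "bd_tree", {
    for (try in seq_len(max_tries)) {
      sim <- simulate_tree_engine(n_tips, c(birth, birth), c(death, death),
                                  c(0, 0), 1L)
      if (is.null(sim)) next
      nk <- engine_to_newick(sim)
      if (is.null(nk) || !startsWith(nk$newick, "(")) next
      tr <- ape::read.tree(text = nk$newick)
      if (ape::Ntip(tr) == n_tips) return(tr)
    }
    abort(sprintf("Birth-death simulation went extinct %d times in a row.",
                  max_tries))
  })
}

#' Simulate a tree and binary tip states under the BiSSE process
#'
#' The binary character (generalist/specialist) evolves jointly with the
#' tree: each state has its own speciation and extinction rate and
#' transitions occur anagenetically along branches.
#'
#' @param pars Named numeric vector of the six rates: `lambda_g`, `lambda_s`
#'   (speciation), `mu_g`, `mu_s` (extinction), `q_gs`, `q_sg` (transition
#'   generalist->specialist and back). All >= 0; at least one speciation rate
#'   positive.
#' @param n_tips Number of extant tips.
#' @param root_state Root character state, `"generalist"` or `"specialist"`.
#' @param seed RNG seed.
#' @param max_tries Retry cap on whole-clade extinction.
#' @return List with `tree` (`ape::phylo`) and `states` (named character
#'   vector over tips, values `"generalist"`/`"specialist"`).
#' @export
simulate_bisse <- function(pars, n_tips, root_state = "generalist", seed = 1,
                           max_tries = 100) {
  need <- c("lambda_g", "lambda_s", "mu_g", "mu_s", "q_gs", "q_sg")
  if (!all(need %in% names(pars))) {
    abort(paste("`pars` must be named:", paste(need, collapse = ", ")))
  }
  pars <- pars[need]
  if (any(pars < 0)) abort("All rates must be >= 0.")
  if (pars["lambda_g"] <= 0 && pars["lambda_s"] <= 0) {
    abort("At least one speciation rate must be positive.")
  }
  assert_count(n_tips, "n_tips", min = 2)
  root <- match.arg(root_state, c("generalist", "specialist"))
  with_stream(seed, "bisse_sim", {
    for (try in seq_len(max_tries)) {
      sim <- simulate_tree_engine(
        n_tips,
        lambda = unname(pars[c("lambda_g", "lambda_s")]),
        mu = unname(pars[c("mu_g", "mu_s")]),
        q = unname(pars[c("q_gs", "q_sg")]),
        root_state = if (root == "generalist") 1L else 2L
      )
      if (is.null(sim)) next
      nk <- engine_to_newick(sim)
      if (is.null(nk) || !startsWith(nk$newick, "(")) next
      tr <- ape::read.tree(text = nk$newick)
      if (ape::Ntip(tr) != n_tips) next
      states <- c("generalist", "specialist")[nk$states]
      names(states) <- paste0("t", seq_along(states))
      return(list(tree = tr, states = states[tr$tip.label]))
    }
    abort(sprintf("BiSSE simulation went extinct %d times in a row.",
                  max_tries))
  })
}

#' Generate count compositions with a known basis correlation
#'
#' Lognormal basis abundances with the requested log-scale correlation
#' structure are closed to compositions and sampled multinomially, providing
#' ground truth for the SparCC stage.
#'
#' @param basis_correlation Symmetric positive semi-definite matrix with unit
#'   diagonal (the true correlation of log basis abundances).
#' @param n_samples Number of samples (columns).
#' @param depth Reads per sample.
#' @param meanlog,sdlog Lognormal location/scale of basis abundances.
#' @param seed RNG seed.
#' @return A [community_table()] (all samples labelled habitat "synthetic").
#' @export
generate_correlated_compositions <- function(basis_correlation, n_samples,
                                             depth, meanlog = 0, sdlog = 1,
                                             seed = 1) {
  assert_count(n_samples, "n_samples")
  if (!is.numeric(depth) || depth <= 0) abort("`depth` must be positive.")
  cm <- as.matrix(basis_correlation)
  if (nrow(cm) != ncol(cm) || max(abs(cm - t(cm))) > 1e-8 ||
        max(abs(diag(cm) - 1)) > 1e-8) {
    abort("`basis_correlation` must be symmetric with unit diagonal.")
  }
  ev <- eigen(cm, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    abort("`basis_correlation` must be positive semi-definite.")
  }
  fac <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(cm))
  with_stream(seed, "compositions", {
    n_taxa <- nrow(cm)
    z <- fac %*% matrix(stats::rnorm(n_taxa * n_samples), n_taxa, n_samples)
    w <- exp(meanlog + sdlog * z)
    counts <- apply(w, 2, function(p) stats::rmultinom(1L, depth, p)[, 1L])
    rownames(counts) <- sprintf("taxon%0*d", nchar(n_taxa), seq_len(n_taxa))
    colnames(counts) <- sprintf("s%0*d", nchar(n_samples), seq_len(n_samples))
    community_table(counts,
                    tibble(sample = colnames(counts), habitat = "synthetic",
                           park = "none", x = 0, y = 0))
  })
}
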