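#' Pipeline configuration
#'
#' Collects every stage's parameters, the input sources (a synthetic design
#' or file paths) and one master seed from which each stage derives its own
#' substream. A configuration can be round-tripped through YAML.
#'
#' @param out_dir Output directory (created if missing).
#' @param design A [synthetic_design()] for the primary (prokaryote-like)
#'   domain, or `NULL` when reading inputs from files.
#' @param euk_design Optional second-domain design for interdomain analyses.
#' @param inputs Named list of file paths (`counts`, `metadata`, `tree`)
#'   used when `design` is `NULL`.
#' @param preprocess,niche,beta,assembly,network,evo Named lists of stage
#'   parameters; missing entries take the defaults shown in Usage.
#' @param stages Character vector of stages to run.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            design = NULL,
                            euk_design = NULL,
                            inputs = list(),
                            preprocess = list(),
                            niche = list(),
                            beta = list(),
                            assembly = list(),
                            network = list(),
                            evo = list(),
                            stages = c("synth", "preprocess", "niche", "beta",
                                       "assembly", "network", "evo"),
                            seed = 1) {
  defaults <- list(
    preprocess = list(min_reads = 10, depth = NULL),
    niche = list(n_perm = 1000, envelope = 0.95, null_method = "shuffle",
                 strict_percentile = 0.9, strict_min_reads = 50),
    beta = list(method = "bray"),
    assembly = list(n_null = 199, group_by = "habitat"),
    network = list(r_min = 0.6, alpha = 0.05, n_bootstrap = 100,
                   min_reads = 50, n_random = 50, removal_fraction = 0.5,
                   removal_reps = 100),
    evo = list(tree_birth = 1, tree_death = 0)
  )
  merge1 <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    out_dir = out_dir, design = design, euk_design = euk_design,
    inputs = inputs,
    preprocess = merge1(preprocess, defaults$preprocess),
    niche = merge1(niche, defaults$niche),
    beta = merge1(beta, defaults$beta),
    assembly = merge1(assembly, defaults$assembly),
    network = merge1(network, defaults$network),
    evo = merge1(evo, defaults$evo),
    stages = stages, seed = seed
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$design)) {
    if ("synth" %in% cfg$stages) {
      abort("Stage `synth` requested but no design given.")
    }
    need <- c("counts", "metadata")
    if ("evo" %in% cfg$stages || "assembly" %in% cfg$stages) {
      need <- c(need, "tree")
    }
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss) > 0) {
      abort(paste0("Missing input paths for: ", paste(miss, collapse = ", ")))
    }
    bad <- !vapply(cfg$inputs[need], file.exists, logical(1))
    if (any(bad)) {
      abort(paste0("Input files not found: ",
                   paste(unlist(cfg$inputs[need][bad]), collapse = ", ")))
    }
  }
  invisible(cfg)
}

#' A small bundled demonstration configuration
#'
#' A scaled-down synthetic design (two domains, 4 parks x 5 habitats x 2
#' replicates, 160 + 120 taxa) that exercises every pipeline stage in a few
#' minutes on one CPU.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(out_dir, seed = 1) {
  pipeline_config(
    out_dir = out_dir,
    design = synthetic_design(n_taxa = 160, n_parks = 4, replicates = 2,
                              depth = 3000, seed = substream_seed(seed, "p")),
    euk_design = synthetic_design(n_taxa = 120, n_parks = 4, replicates = 2,
                                  depth = 3000,
                                  seed = substream_seed(seed, "m")),
    niche = list(n_perm = 300),
    assembly = list(n_null = 149),
    network = list(n_bootstrap = 60, n_random = 30, removal_reps = 50),
    seed = seed
  )
}

write_tsv_det <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# plain-list view of a config for YAML serialisation
config_to_plain <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, config_to_plain)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.function(x)) NULL else unclass(x)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order (synthesis or input
#' loading, table filters, niche classification, distance decay, assembly
#' partitioning, network inference and stability, BiSSE diversification),
#' writing each stage's outputs as TSV (trees as Newick, the resolved
#' configuration as YAML) into `out_dir`, and returns a manifest of all
#' artifacts with their MD5 hashes. Reruns with an identical configuration
#' are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return Tibble manifest (stage, file, md5), invisibly also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  say <- function(...) if (!quiet) message("[habgen] ", sprintf(...))
  files <- list()
  note <- function(stage, path) {
    files[[length(files) + 1]] <<- tibble(stage = stage, file = basename(path))
  }
  run_stage <- function(stage, expr) {
    say("stage %s", stage)
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  seed <- config$seed

  # --- inputs / synthesis ----------------------------------------------
  truth <- euk <- NULL
  if (!is.null(config$design)) {
    gen <- run_stage("synth", generate_community(config$design))
    table <- gen$table; truth <- gen$truth
    tree <- generate_bd_tree(config$design$n_taxa,
                             birth = config$evo$tree_birth,
                             death = config$evo$tree_death,
                             seed = substream_seed(seed, "tree"))
    tree$tip.label <- rownames(table$counts)[seq_len(config$design$n_taxa)]
    if ("synth" %in% config$stages) {
      write_community_tsv(table, out("counts.tsv"), out("metadata.tsv"))
      write_tsv_det(truth, out("truth.tsv"))
      ape::write.tree(tree, out("tree.nwk"))
      note("synth", out("counts.tsv")); note("synth", out("metadata.tsv"))
      note("synth", out("truth.tsv")); note("synth", out("tree.nwk"))
    }
    if (!is.null(config$euk_design)) {
      geneuk <- generate_community(config$euk_design)
      euk <- geneuk$table
      if ("synth" %in% config$stages) {
        write_community_tsv(euk, out("euk_counts.tsv"))
        write_tsv_det(geneuk$truth, out("euk_truth.tsv"))
        note("synth", out("euk_counts.tsv"))
        note("synth", out("euk_truth.tsv"))
      }
    }
  } else {
    table <- read_community_tsv(config$inputs$counts, config$inputs$metadata)
    tree <- if (!is.null(config$inputs$tree)) {
      ape::read.tree(config$inputs$tree)
    } else NULL
    if (!is.null(config$inputs$euk_counts)) {
      euk <- read_community_tsv(config$inputs$euk_counts,
                                config$inputs$metadata)
    }
  }

  # --- preprocess -------------------------------------------------------
  if ("preprocess" %in% config$stages) {
    run_stage("preprocess", {
      table <- filter_min_reads(table, config$preprocess$min_reads)
      table <- rarefy(table, depth = config$preprocess$depth,
                      seed = substream_seed(seed, "rarefy"))
      if (!is.null(euk)) {
        euk <- filter_min_reads(euk, config$preprocess$min_reads)
        euk <- rarefy(euk, depth = config$preprocess$depth,
                      seed = substream_seed(seed, "rarefy_euk"))
      }
      cov <- goods_coverage(table)
      write_tsv_det(cov, out("goods_coverage.tsv"))
      note("preprocess", out("goods_coverage.tsv"))
    })
  }

  # --- niche classification --------------------------------------------
  profiles <- euk_profiles <- NULL
  if ("niche" %in% config$stages) {
    run_stage("niche", {
      np <- config$niche
      profiles <- null_classify(table, n_perm = np$n_perm,
                                 envelope = np$envelope,
                                 null_method = np$null_method,
                                 seed = substream_seed(seed, "niche")) |>
        strict_filter(percentile = np$strict_percentile,
                      min_reads = np$strict_min_reads)
      write_tsv_det(profiles, out("niche_profiles.tsv"))
      note("niche", out("niche_profiles.tsv"))
      if (!is.null(euk)) {
        euk_profiles <- null_classify(euk, n_perm = np$n_perm,
                                       envelope = np$envelope,
                                       null_method = np$null_method,
                                       seed = substream_seed(seed,
                                                             "niche_euk")) |>
          strict_filter(percentile = np$strict_percentile,
                        min_reads = np$strict_min_reads)
        write_tsv_det(euk_profiles, out("euk_niche_profiles.tsv"))
        note("niche", out("euk_niche_profiles.tsv"))
      }
    })
  }

  # --- distance decay ---------------------------------------------------
  if ("beta" %in% config$stages && !is.null(profiles)) {
    run_stage("beta", {
      groups <- list(
        generalist = profiles$taxon[profiles$class_strict == "generalist"],
        specialist = profiles$taxon[profiles$class_strict == "specialist"])
      groups <- groups[vapply(groups, length, integer(1)) >= 3]
      if (length(groups) > 0) {
        decay <- distance_decay_by_group(table, groups,
                                         method = config$beta$method)
        write_tsv_det(decay, out("distance_decay.tsv"))
        note("beta", out("distance_decay.tsv"))
      }
    })
  }

  # --- community assembly ----------------------------------------------
  if ("assembly" %in% config$stages && !is.null(tree)) {
    run_stage("assembly", {
      pairs <- assembly_pairs(table, tree,
                              group_by = config$assembly$group_by,
                              n_null = config$assembly$n_null,
                              seed = substream_seed(seed, "assembly"))
      write_tsv_det(pairs, out("assembly_pairs.tsv"))
      note("assembly", out("assembly_pairs.tsv"))
      write_tsv_det(summarize_assembly(pairs), out("assembly_summary.tsv"))
      note("assembly", out("assembly_summary.tsv"))
    })
  }

  # --- networks ---------------------------------------------------------
  if ("network" %in% config$stages && !is.null(profiles)) {
    run_stage("network", {
      nw <- config$network
      abun <- filter_min_reads(table, nw$min_reads)
      rho <- sparcc(abun, seed = substream_seed(seed, "sparcc"))
      pv <- edge_pvalues(abun, n_bootstrap = nw$n_bootstrap,
                         seed = substream_seed(seed, "sparcc_p"))
      ann <- tibble(taxon = profiles$taxon, domain = "prokaryote",
                    niche_class = profiles$class_strict)
      g <- threshold_network(rho, pv, ann, r_min = nw$r_min,
                             alpha = nw$alpha)
      if (igraph::ecount(g) > 0) {
        edges <- igraph::as_data_frame(g, what = "edges")
        write_tsv_det(edges, out("network_edges.tsv"))
        note("network", out("network_edges.tsv"))
        write_tsv_det(topo_props(g), out("network_stats.tsv"))
        note("network", out("network_stats.tsv"))
        roles <- zi_pi(g)
        write_tsv_det(roles, out("node_roles.tsv"))
        note("network", out("node_roles.tsv"))
        cls <- stats::setNames(profiles$class_strict, profiles$taxon)
        write_tsv_det(keystone_tally(roles, cls), out("keystone_tally.tsv"))
        note("network", out("keystone_tally.tsv"))
        if (igraph::ecount(g) >= 2) {
          rn <- rewire_null(g, n_random = nw$n_random,
                            seed = substream_seed(seed, "rewire"))
          write_tsv_det(rn$summary, out("network_null.tsv"))
          note("network", out("network_null.tsv"))
        }
        stab <- purrr::map(intersect(c("generalist", "specialist"),
                                     unique(igraph::V(g)$niche_class)),
                           function(k) {
          removal_experiment(g, k, fraction = nw$removal_fraction,
                             reps = nw$removal_reps,
                             seed = substream_seed(seed, paste0("rm_", k)))
        }) |> bind_rows()
        if (nrow(stab) > 0) {
          stab$vulnerability <- vulnerability(g)
          stab$robustness <- robustness(g, reps = nw$removal_reps,
                                        seed = substream_seed(seed, "rob"))
          write_tsv_det(stab, out("stability.tsv"))
          note("network", out("stability.tsv"))
        }
      }
      if (!is.null(euk) && !is.null(euk_profiles) &&
            any(euk_profiles$class_strict != "opportunist") &&
            any(profiles$class_strict != "opportunist")) {
        ig <- interdomain_network(table, euk, profiles, euk_profiles,
                                  r_min = nw$r_min, alpha = nw$alpha,
                                  n_bootstrap = nw$n_bootstrap,
                                  seed = substream_seed(seed, "interdomain"))
        if (igraph::ecount(ig) > 0) {
          write_tsv_det(igraph::as_data_frame(ig, what = "edges"),
                        out("interdomain_edges.tsv"))
          note("network", out("interdomain_edges.tsv"))
          write_tsv_det(
            tibble(functional_complementarity =
                     functional_complementarity(ig),
                   niche_overlap = niche_overlap(ig)),
            out("interdomain_stats.tsv"))
          note("network", out("interdomain_stats.tsv"))
        }
      }
    })
  }

  # --- diversification --------------------------------------------------
  if ("evo" %in% config$stages && !is.null(profiles) && !is.null(tree)) {
    run_stage("evo", {
      cls <- stats::setNames(profiles$class_strict, profiles$taxon)
      keep <- names(cls)[cls %in% c("generalist", "specialist") &
                           names(cls) %in% tree$tip.label]
      if (length(keep) >= 3 &&
            length(unique(cls[keep])) == 2) {
        sub <- ape::keep.tip(tree, keep)
        states <- cls[sub$tip.label]
        fit <- bisse_fit(sub, states, seed = substream_seed(seed, "bisse"))
        write_tsv_det(glance(fit), out("bisse_fit.tsv"))
        note("evo", out("bisse_fit.tsv"))
        write_tsv_det(tidy(fit), out("bisse_rates.tsv"))
        note("evo", out("bisse_rates.tsv"))
        write_tsv_det(root_to_tip_lengths(sub, states),
                      out("root_to_tip.tsv"))
        note("evo", out("root_to_tip.tsv"))
      } else {
        write_tsv_det(tibble(note = "too few strict taxa for a BiSSE fit"),
                      out("bisse_fit.tsv"))
        note("evo", out("bisse_fit.tsv"))
      }
    })
  }

  # --- manifest ---------------------------------------------------------
  yaml::write_yaml(config_to_plain(config), out("config_resolved.yaml"))
  note("config", out("config_resolved.yaml"))
  manifest <- bind_rows(files)
  manifest$md5 <- unname(tools::md5sum(file.path(config$out_dir,
                                                 manifest$file)))
  write_tsv_det(manifest, out("manifest.tsv"))
  say("done: %d artifacts in %s", nrow(manifest), config$out_dir)
  manifest
}
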