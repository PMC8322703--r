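# Pipeline orchestration: a validated config drives the six analysis stages
# (de -> rra -> network -> hubs -> cerna -> enrich) over either synthetic
# inputs with planted truth or user-supplied files; every stage writes its
# TSV/JSON artifacts, everything is logged, and a manifest records each
# artifact with a content hash. One global seed is fanned out to the
# stochastic stages by fixed offsets so each stage is individually
# reproducible.

config_ranges <- list(
  lfc_cut = c(0, Inf), p_cut = c(0, 1), rra_score_cut = c(0, 1),
  hub_score_cut = c(0, 1), min_conf = c(0, 1), top_k = c(1, Inf),
  mcode_node_score_cut = c(0, 1), mcode_k_core = c(0, Inf),
  epc_iters = c(1, Inf), epc_keep_p = c(0, 1), ora_alpha = c(0, 1)
)

#' Build a validated pipeline configuration
#'
#' Thresholds default to the study values (fold-change 0.5, p 0.05, RRA
#' score 0.05, interaction confidence 0.4, per-method top-50 lists); every
#' field is range-checked and unknown fields are rejected by
#' [validate_config()].
#'
#' @param output_dir Directory for stage artifacts, the log, and the
#'   manifest.
#' @param seed Global integer seed, fanned out per stage.
#' @param lfc_cut,p_cut Per-dataset DEG cuts (strict inequalities).
#' @param rra_score_cut Robust-DEG corrected-score cut.
#' @param hub_score_cut Hub corrected-score cut.
#' @param min_conf Interaction-confidence cut (strict `>`).
#' @param top_k Per-centrality list length.
#' @param mcode_node_score_cut,mcode_k_core MCODE parameters.
#' @param epc_iters,epc_keep_p EPC Monte-Carlo parameters.
#' @param ora_alpha Enrichment significance cut.
#' @param simulate Named list of overrides for the synthetic generators
#'   (fields of [simulate_expression_datasets()], [simulate_ppi()],
#'   [simulate_cerna_tables()]); used when `inputs` is `NULL`.
#' @param inputs Named list of input paths for a file-driven run:
#'   `expression` and `group_maps` (parallel path vectors), optional
#'   `annotations`, plus `ppi_edges`, `targets`, `demis`, `circ` and
#'   optional `gene_sets` (GMT).
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1L, lfc_cut = 0.5, p_cut = 0.05,
                            rra_score_cut = 0.05, hub_score_cut = 0.05,
                            min_conf = 0.4, top_k = 50,
                            mcode_node_score_cut = 0.2, mcode_k_core = 2,
                            epc_iters = 1000, epc_keep_p = 0.5,
                            ora_alpha = 0.05, simulate = list(), inputs = NULL) {
  config <- list(
    output_dir = output_dir, seed = as.integer(seed), lfc_cut = lfc_cut,
    p_cut = p_cut, rra_score_cut = rra_score_cut,
    hub_score_cut = hub_score_cut, min_conf = min_conf, top_k = top_k,
    mcode_node_score_cut = mcode_node_score_cut, mcode_k_core = mcode_k_core,
    epc_iters = epc_iters, epc_keep_p = epc_keep_p, ora_alpha = ora_alpha,
    simulate = simulate, inputs = inputs
  )
  validate_config(config)
}

#' Validate a pipeline configuration
#'
#' Rejects unknown fields and out-of-range thresholds, naming the offending
#' field.
#'
#' @param config A list of [pipeline_config()] fields.
#' @return The config, classed `pipeline_config`, invisibly usable.
#' @export
validate_config <- function(config) {
  allowed <- c(
    "output_dir", "seed", names(config_ranges), "simulate", "inputs"
  )
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$output_dir)) abort("config field output_dir is required.")
  for (f in names(config_ranges)) {
    v <- config[[f]]
    if (is.null(v)) abort(sprintf("config field %s is required.", f))
    r <- config_ranges[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < r[1] || v > r[2]) {
      abort(sprintf(
        "config field %s = %s is outside its allowed range [%g, %g].",
        f, format(v), r[1], r[2]
      ))
    }
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    abort("config field seed must be a single integer.")
  }
  structure(config, class = c("pipeline_config", "list"))
}

pipeline_log <- function(state, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  cat(line, "\n", file = state$log_path, append = TRUE, sep = "")
  invisible(state)
}

register_artifact <- function(state, stage, name, path) {
  state$manifest[[length(state$manifest) + 1]] <- list(
    stage = stage, artifact = name, path = basename(path),
    md5 = unname(tools::md5sum(path))
  )
  state
}

# Stage seed fan-out: fixed offsets from the global seed.
stage_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

load_pipeline_inputs <- function(config) {
  inp <- config$inputs
  if (is.null(inp)) {
    sim_args <- function(defaults, overrides) {
      utils::modifyList(defaults, overrides[intersect(names(overrides), names(defaults))])
    }
    ex <- do.call(simulate_expression_datasets, sim_args(
      formals_defaults(simulate_expression_datasets, seed = stage_seed(config, 0L)),
      config$simulate
    ))
    return(list(mode = "simulate", expression = ex))
  }
  required <- c("expression", "group_maps", "ppi_edges", "targets", "demis", "circ")
  for (f in required) {
    if (is.null(inp[[f]])) abort(sprintf("input field %s is required.", f))
  }
  paths <- c(
    inp$expression, inp$group_maps, inp$annotations, inp$ppi_edges,
    inp$targets, inp$demis, inp$circ, inp$gene_sets
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  }
  datasets <- lapply(seq_along(inp$expression), function(i) {
    m <- read_expression_table(inp$expression[i], inp$group_maps[i])
    if (!is.null(inp$annotations)) {
      m <- collapse_probes(m, read_probe_annotation(inp$annotations[i]))
    }
    suppressMessages(ensure_log2(m))
  })
  names(datasets) <- sprintf("DS%d", seq_along(datasets))
  list(mode = "files", expression = list(datasets = datasets, truth = NULL))
}

formals_defaults <- function(fn, ...) {
  d <- as.list(formals(fn))
  d <- d[!vapply(d, is.symbol, logical(1))]
  d <- lapply(d, eval, envir = baseenv())
  utils::modifyList(d, list(...))
}

#' Run the full pipeline
#'
#' Executes the six stages in order — per-dataset moderated-t differential
#' expression, RRA integration into robust DEGs, interaction-network
#' construction with MCODE complex detection, ten-centrality hub
#' identification, ceRNA network assembly, and hypergeometric enrichment —
#' writing each stage's artifacts plus a log to `output_dir` and returning a
#' manifest of artifact paths and MD5 content hashes. With `inputs = NULL`
#' every input is generated by the seeded synthetic generators (planted
#' truth is saved alongside); re-running with the same config yields
#' byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Tibble manifest (`stage`, `artifact`, `path`, `md5`), invisibly;
#'   also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$manifest <- list()
  state$log_path <- file.path(config$output_dir, "pipeline.log")
  cat("", file = state$log_path) # truncate
  art <- function(name) file.path(config$output_dir, name)
  loaded <- load_pipeline_inputs(config)
  simulate_mode <- loaded$mode == "simulate"
  datasets <- loaded$expression$datasets
  truth <- loaded$expression$truth
  pipeline_log(state, sprintf(
    "inputs: %s mode, %d expression dataset(s), seed %d",
    loaded$mode, length(datasets), config$seed
  ))

  # ---- stage de ----
  fits <- lapply(datasets, moderated_t_test)
  for (nm in names(fits)) {
    p <- art(sprintf("de_%s.tsv", nm))
    write_de_table(fits[[nm]], p)
    state <- register_artifact(state, "de", sprintf("de_%s", nm), p)
  }
  pipeline_log(state, sprintf("de: fitted %d dataset(s)", length(fits)))

  # ---- stage rra ----
  deg_lists <- lapply(fits, filter_degs, lfc = config$lfc_cut, alpha = config$p_cut)
  universes <- vapply(fits, function(f) nrow(f$table), numeric(1))
  lfc_long <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble(item = f$table$gene, log2fc = f$table$log2fc)
  }))
  rra_up <- rra_aggregate(lapply(deg_lists, `[[`, "up"), universes, lfc_long)
  rra_down <- rra_aggregate(lapply(deg_lists, `[[`, "down"), universes, lfc_long)
  robust <- select_robust(rra_up, rra_down,
    score_cut = config$rra_score_cut, lfc_cut = config$lfc_cut
  )
  p <- art("robust_degs.tsv")
  write_rra_table(robust, p)
  state <- register_artifact(state, "rra", "robust_degs", p)
  pipeline_log(state, sprintf(
    "rra: %d robust DEGs (%d up, %d down)",
    nrow(robust), sum(robust$direction == "up"), sum(robust$direction == "down")
  ))

  # ---- stage network ----
  if (simulate_mode) {
    # plant the interaction cliques on planted DE genes so the induced DEG
    # network and downstream hubs connect to the expression truth
    sizes <- config$simulate$clique_sizes %||% c(6, 5)
    planted_genes <- c(truth$up, truth$down)
    backbone <- c(
      planted_genes[seq_len(min(sum(sizes), length(planted_genes)))],
      setdiff(planted_genes, planted_genes[seq_len(sum(sizes))]),
      setdiff(truth$genes, planted_genes)
    )
    ppi <- simulate_ppi(
      n_background = config$simulate$n_background %||% 60,
      p_edge = config$simulate$p_edge %||% 0.05,
      clique_sizes = sizes,
      seed = stage_seed(config, 1L),
      node_names = backbone
    )$network
  } else {
    ppi <- load_edge_list(config$inputs$ppi_edges, min_conf = config$min_conf)
  }
  net <- suppressWarnings(induce_on_genes(ppi, robust$item))
  clusters <- mcode_find_clusters(net,
    node_score_cut = config$mcode_node_score_cut, k_core = config$mcode_k_core
  )
  p <- art("network_edges.tsv")
  write_edge_list(net, p)
  state <- register_artifact(state, "network", "network_edges", p)
  p <- art("mcode_clusters.tsv")
  readr::write_tsv(
    dplyr::mutate(clusters, nodes = vapply(nodes, paste, character(1), collapse = ",")),
    p
  )
  state <- register_artifact(state, "network", "mcode_clusters", p)
  pipeline_log(state, sprintf(
    "network: %d nodes, %d edges, %d MCODE cluster(s)",
    igraph::vcount(net), igraph::ecount(net), nrow(clusters)
  ))

  # ---- stage hubs ----
  hub_res <- identify_hubs(net,
    top_k = config$top_k, score_cut = config$hub_score_cut,
    seed = stage_seed(config, 2L),
    epc_iters = config$epc_iters, epc_keep_p = config$epc_keep_p
  )
  p <- art("centrality.tsv")
  readr::write_tsv(hub_res$centralities, p)
  state <- register_artifact(state, "hubs", "centrality", p)
  p <- art("hubs.tsv")
  readr::write_tsv(hub_res$hubs, p)
  state <- register_artifact(state, "hubs", "hubs", p)
  pipeline_log(state, sprintf("hubs: %d hub gene(s)", nrow(hub_res$hubs)))

  # ---- stage cerna ----
  hub_genes <- hub_res$hubs$node
  hub_dirs <- setNames(
    robust$direction[match(hub_genes, robust$item)], hub_genes
  )
  hub_dirs <- hub_dirs[!is.na(hub_dirs)]
  if (simulate_mode) {
    n_trip <- min(5L, max(1L, length(hub_dirs)))
    ce <- simulate_cerna_tables(
      n_planted_triplets = n_trip,
      seed = stage_seed(config, 3L),
      mrna_names = names(hub_dirs), mrna_directions = unname(hub_dirs)
    )
    targets <- ce$targets
    demis <- ce$demis
    circ <- ce$circ
    mrna_dirs <- ce$truth$mrna_dirs
  } else {
    # target predictions are made for the hub genes; restrict accordingly
    targets <- read_target_table(config$inputs$targets)
    targets <- targets[targets$mrna %in% names(hub_dirs), , drop = FALSE]
    demis <- read_demi_table(config$inputs$demis)
    circ <- read_circ_table(config$inputs$circ)
    mrna_dirs <- hub_dirs
  }
  if (!length(hub_dirs)) {
    abort("no hub genes at the configured score cut; cannot run the cerna stage.")
  }
  cerna <- suppressWarnings(assemble_cerna(targets, demis, mrna_dirs, circ))
  write_cerna_network(cerna,
    nodes_path = art("cerna_nodes.tsv"),
    edges_path = art("cerna_edges.tsv"),
    json_path = art("cerna_network.json")
  )
  for (nm in c("cerna_nodes.tsv", "cerna_edges.tsv", "cerna_network.json")) {
    state <- register_artifact(state, "cerna", sub("\\.(tsv|json)$", "", nm), art(nm))
  }
  top_ce <- rank_cerna_mcc(cerna, top = 10)
  p <- art("cerna_mcc_top.tsv")
  readr::write_tsv(tibble(rank = seq_along(top_ce), node = top_ce), p)
  state <- register_artifact(state, "cerna", "cerna_mcc_top", p)
  pipeline_log(state, sprintf(
    "cerna: %s", paste(utils::capture.output(print(cerna)), collapse = " ")
  ))

  # ---- stage enrich ----
  if (simulate_mode) {
    universe <- truth$genes
    gene_sets <- c(
      list(planted_up = truth$up, planted_down = truth$down),
      withr::with_seed(stage_seed(config, 4L), {
        setNames(
          lapply(1:8, function(i) sample(universe, 40)),
          sprintf("random_set_%02d", 1:8)
        )
      })
    )
  } else {
    universe <- unique(unlist(lapply(fits, function(f) f$table$gene)))
    gene_sets <- if (!is.null(config$inputs$gene_sets)) {
      read_gmt(config$inputs$gene_sets)
    } else {
      abort("input field gene_sets is required for the enrich stage.")
    }
  }
  enr <- ora(robust$item, gene_sets, universe, alpha = config$ora_alpha)
  p <- art("enrichment.tsv")
  readr::write_tsv(
    dplyr::mutate(enr, hits = vapply(hits, paste, character(1), collapse = ",")),
    p
  )
  state <- register_artifact(state, "enrich", "enrichment", p)
  pipeline_log(state, sprintf(
    "enrich: %d/%d set(s) significant at p < %g",
    sum(enr$significant), nrow(enr), config$ora_alpha
  ))

  manifest <- dplyr::bind_rows(lapply(state$manifest, as_tibble))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  pipeline_log(state, sprintf("done: %d artifact(s)", nrow(manifest)))
  invisible(manifest)
}
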