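# Seeded synthetic-data generators with planted ground truth. Each emulates
# one class of pipeline input: multi-cohort case/control log2 expression
# matrices with concordant planted DE genes, a confidence-scored interaction
# network with planted cliques, and the target/DEMi/circRNA tables of the
# ceRNA stage with planted triplets and single-rule-violating decoys.
# Every generator is a pure function of its parameters and seed (the global
# RNG state is untouched).

#' Simulate case/control expression datasets with planted DE genes
#'
#' Each dataset draws gene values from `Normal(baseline_g, sigma^2)` around
#' a shared per-gene baseline (itself `Normal(7, 1)`, a typical log2
#' microarray intensity); planted genes are shifted by `+effect` (up) or
#' `-effect` (down) in the case group of every dataset in which they are
#' measured. A fraction `missing_frac` of genes is absent from each dataset,
#' emulating platform differences.
#'
#' @param n_datasets Number of datasets (default 5).
#' @param n_genes Shared gene-space size (default 1000).
#' @param n_case,n_control Samples per group per dataset (default 20 each).
#' @param n_up,n_down Planted up/down gene counts (default 50 each;
#'   `n_up + n_down < n_genes`).
#' @param effect Case-group shift on the log2 scale (default 1.0).
#' @param sigma Within-group standard deviation (default 1.0).
#' @param missing_frac Fraction of genes absent per dataset (default 0.1).
#' @param seed Integer seed.
#'
#' @return List with `datasets` (list of [expr_matrix()]) and `truth`
#'   (list: `up`, `down`, `effect`, `genes`).
#' @export
simulate_expression_datasets <- function(n_datasets = 5, n_genes = 1000,
                                         n_case = 20, n_control = 20,
                                         n_up = 50, n_down = 50,
                                         effect = 1.0, sigma = 1.0,
                                         missing_frac = 0.1, seed = 1) {
  if (n_up + n_down >= n_genes) abort("n_up + n_down must be smaller than n_genes.")
  if (n_case < 2 || n_control < 2) abort("need at least 2 samples per group.")
  if (missing_frac < 0 || missing_frac >= 1) abort("missing_frac must be in [0, 1).")
  withr::with_seed(seed, {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    baseline <- setNames(rnorm(n_genes, mean = 7, sd = 1), genes)
    planted <- sample(genes, n_up + n_down)
    up <- sort(planted[seq_len(n_up)])
    down <- sort(planted[n_up + seq_len(n_down)])
    datasets <- lapply(seq_len(n_datasets), function(d) {
      absent <- if (missing_frac > 0) sample(genes, round(missing_frac * n_genes)) else character()
      present <- setdiff(genes, absent)
      ns <- n_case + n_control
      v <- matrix(rnorm(length(present) * ns, sd = sigma), nrow = length(present)) +
        baseline[present]
      samples <- c(
        sprintf("DS%d_case%02d", d, seq_len(n_case)),
        sprintf("DS%d_ctrl%02d", d, seq_len(n_control))
      )
      dimnames(v) <- list(present, samples)
      case_cols <- seq_len(n_case)
      v[present %in% up, case_cols] <- v[present %in% up, case_cols] + effect
      v[present %in% down, case_cols] <- v[present %in% down, case_cols] - effect
      expr_matrix(v, setNames(rep(c("case", "control"), c(n_case, n_control)), samples))
    })
    names(datasets) <- sprintf("DS%d", seq_len(n_datasets))
    list(
      datasets = datasets,
      truth = list(up = up, down = down, effect = effect, genes = genes)
    )
  })
}

#' Simulate a confidence-scored interaction network with planted cliques
#'
#' An Erdős–Rényi background `G(n, p_edge)` plus fully connected planted
#' cliques; clique-to-background and background pairs appear with
#' probability `p_edge`, so `p_edge = 0` yields exactly the planted
#' cliques. Within-clique edges get confidence `Uniform(0.7, 1)`, all other
#' edges `Uniform(0.2, 0.9)`.
#'
#' @param n_background Background node count (default 60).
#' @param p_edge Background edge probability (default 0.05).
#' @param clique_sizes Sizes of the planted cliques (default `c(6, 5)`).
#' @param seed Integer seed.
#' @param node_names Optional node names; the first `sum(clique_sizes)`
#'   become the clique nodes, the rest the background. Auto-generated when
#'   `NULL`.
#'
#' @return List with `network` (igraph, edge attribute `confidence`) and
#'   `truth` (list: `cliques`, a list of node-name vectors).
#' @export
simulate_ppi <- function(n_background = 60, p_edge = 0.05,
                         clique_sizes = c(6, 5), seed = 1, node_names = NULL) {
  if (p_edge < 0 || p_edge > 1) abort("p_edge must be in [0, 1].")
  if (any(clique_sizes < 2)) abort("clique sizes must be at least 2.")
  n_cl <- sum(clique_sizes)
  n_tot <- n_background + n_cl
  if (is.null(node_names)) {
    node_names <- c(
      unlist(lapply(seq_along(clique_sizes), function(i) {
        sprintf("HUB%d_%02d", i, seq_len(clique_sizes[i]))
      })),
      sprintf("BG%03d", seq_len(n_background))
    )
  }
  if (length(node_names) < n_tot) {
    abort(sprintf("need at least %d node names.", n_tot))
  }
  node_names <- node_names[seq_len(n_tot)]
  if (anyDuplicated(node_names)) abort("node names must be unique.")
  cliques <- split(
    node_names[seq_len(n_cl)],
    rep(seq_along(clique_sizes), clique_sizes)
  )
  names(cliques) <- NULL
  in_same_clique <- function(i, j) {
    ci <- rep(c(seq_along(clique_sizes), 0L), c(clique_sizes, n_background))
    ci[i] != 0L & ci[i] == ci[j]
  }
  withr::with_seed(seed, {
    pr <- t(utils::combn(n_tot, 2))
    same <- in_same_clique(pr[, 1], pr[, 2])
    present <- same | (runif(nrow(pr)) < p_edge)
    pr <- pr[present, , drop = FALSE]
    same <- same[present]
    conf <- ifelse(same, runif(nrow(pr), 0.7, 1), runif(nrow(pr), 0.2, 0.9))
    edges <- tibble(
      a = node_names[pr[, 1]], b = node_names[pr[, 2]], confidence = conf
    )
    g <- igraph::graph_from_data_frame(edges,
      directed = FALSE,
      vertices = tibble(name = node_names)
    )
    list(network = g, truth = list(cliques = cliques))
  })
}

#' Simulate ceRNA-stage input tables with planted triplets and decoys
#'
#' Planted (circRNA, miRNA, mRNA) triplets appear in all three target
#' sources with direction-consistent miRNA DE entries, and every planted
#' circRNA is linked to all planted miRNAs so it covers all planted mRNAs.
#' Decoys each violate exactly one filter: type A pairs are missing from one
#' target source (fail the three-database intersection), type B miRNAs move
#' in the same direction as their target (fail direction validation), and
#' type C circRNAs cover only a strict subset of the planted miRNAs (fail
#' the coverage filter). Background rows pad the tables to `n_mirnas`
#' miRNAs and `n_circ` circRNAs without ever reaching three sources.
#'
#' @param n_mirnas Total miRNA universe size (default 100).
#' @param n_circ Total circRNA count (default 20).
#' @param n_planted_triplets Planted mRNA/miRNA pair count (default 5).
#' @param decoy_frac Decoys per rule as a fraction of the planted count
#'   (default 0.5, rounded up).
#' @param seed Integer seed.
#' @param mrna_names Optional mRNA names for the planted genes (first
#'   `n_planted_triplets` used); synthetic names when `NULL`.
#' @param mrna_directions Optional directions matching `mrna_names`.
#'
#' @return List with `targets` (tibble `mirna`, `mrna`, `source`), `demis`
#'   (tibble `mirna`, `log2fc`, `p`, `direction`), `circ` (tibble
#'   `circrna`, `mirna`) and `truth` (planted pairs/circs, decoys, and the
#'   `mrna_dirs` lookup).
#' @export
simulate_cerna_tables <- function(n_mirnas = 100, n_circ = 20,
                                  n_planted_triplets = 5, decoy_frac = 0.5,
                                  seed = 1, mrna_names = NULL,
                                  mrna_directions = NULL) {
  npt <- n_planted_triplets
  if (npt < 1) abort("need at least one planted triplet.")
  nd <- ceiling(decoy_frac * npt)
  n_pc <- min(3L, max(1L, n_circ - nd)) # planted circRNAs
  if (n_circ < n_pc + nd) abort("n_circ too small for planted circRNAs plus decoys.")
  if (n_mirnas < npt + 2 * nd) abort("n_mirnas too small for planted miRNAs plus decoys.")
  sources <- c("targetscan", "mirdb", "mirwalk")
  if (is.null(mrna_names)) {
    mrna_names <- sprintf("CEGENE%02d", seq_len(npt))
    mrna_directions <- rep(c("up", "down"), length.out = npt)
  } else {
    if (length(mrna_names) < npt) abort("need at least n_planted_triplets mRNA names.")
    mrna_names <- mrna_names[seq_len(npt)]
    if (is.null(mrna_directions) || length(mrna_directions) < npt) {
      abort("`mrna_directions` must accompany `mrna_names`.")
    }
    mrna_directions <- mrna_directions[seq_len(npt)]
    check_direction(mrna_directions, "mRNA")
  }
  withr::with_seed(seed, {
    mi_ids <- sprintf("hsa-miR-S%03d", seq_len(n_mirnas))
    planted_mi <- mi_ids[seq_len(npt)]
    decoyB_mi <- mi_ids[npt + seq_len(nd)]
    decoyA_mi <- mi_ids[npt + nd + seq_len(nd)]
    bg_mi <- setdiff(mi_ids, c(planted_mi, decoyB_mi, decoyA_mi))
    circ_ids <- sprintf("hsa_circ_S%04d", seq_len(n_circ))
    planted_circ <- circ_ids[seq_len(n_pc)]
    decoy_circ <- circ_ids[n_pc + seq_len(nd)]
    bg_circ <- setdiff(circ_ids, c(planted_circ, decoy_circ))

    decoyA_gene <- sprintf("DECOYA%02d", seq_len(nd))
    decoyB_gene <- sprintf("DECOYB%02d", seq_len(nd))
    decoyA_dir <- rep(c("down", "up"), length.out = nd)
    decoyB_dir <- rep(c("up", "down"), length.out = nd)

    opp <- function(d) ifelse(d == "up", "down", "up")

    # target predictions
    planted_targets <- tidyr::expand_grid(
      mirna = planted_mi, source = sources
    ) |>
      dplyr::mutate(mrna = rep(mrna_names, each = length(sources))) |>
      dplyr::select("mirna", "mrna", "source")
    decoyA_targets <- dplyr::bind_rows(lapply(seq_len(nd), function(i) {
      tibble(
        mirna = decoyA_mi[i], mrna = decoyA_gene[i],
        source = sample(sources, 2) # one source withheld
      )
    }))
    decoyB_targets <- tidyr::expand_grid(src = sources, i = seq_len(nd)) |>
      dplyr::transmute(
        mirna = decoyB_mi[.data$i], mrna = decoyB_gene[.data$i],
        source = .data$src
      )
    n_bg_pairs <- max(0L, length(bg_mi))
    bg_targets <- if (n_bg_pairs) {
      dplyr::bind_rows(lapply(seq_len(n_bg_pairs), function(i) {
        tibble(
          mirna = bg_mi[i],
          mrna = sprintf("BGGENE%03d", sample(50, 1)),
          source = sample(sources, sample(2, 1)) # never all three
        )
      }))
    } else {
      tibble(mirna = character(), mrna = character(), source = character())
    }
    targets <- dplyr::bind_rows(planted_targets, decoyA_targets, decoyB_targets, bg_targets)

    # miRNA differential expression; direction consistent with log2fc sign
    mi_dir <- c(
      setNames(opp(mrna_directions), planted_mi),
      setNames(decoyB_dir, decoyB_mi), # same direction as target: decoy rule B
      setNames(opp(decoyA_dir), decoyA_mi),
      setNames(sample(c("up", "down"), length(bg_mi), replace = TRUE), bg_mi)
    )
    demis <- tibble(
      mirna = names(mi_dir),
      log2fc = ifelse(mi_dir == "up", 1, -1) * runif(length(mi_dir), 0.6, 2.5),
      p = runif(length(mi_dir), 1e-5, 0.04),
      direction = unname(mi_dir)
    )

    # circRNA links: planted circs cover every planted miRNA; decoy circs a
    # strict subset (one planted miRNA withheld); background circs touch
    # background miRNAs only
    circ <- dplyr::bind_rows(
      tidyr::expand_grid(circrna = planted_circ, mirna = planted_mi),
      if (npt >= 2) {
        dplyr::bind_rows(lapply(seq_len(nd), function(i) {
          tibble(
            circrna = decoy_circ[i],
            mirna = planted_mi[-(1 + (i - 1) %% npt)]
          )
        }))
      },
      if (length(bg_circ) && length(bg_mi)) {
        dplyr::bind_rows(lapply(bg_circ, function(cc) {
          tibble(circrna = cc, mirna = sample(bg_mi, min(3, length(bg_mi))))
        }))
      }
    )
    circ <- dplyr::distinct(circ)

    mrna_dirs <- c(
      setNames(mrna_directions, mrna_names),
      setNames(decoyA_dir, decoyA_gene),
      setNames(decoyB_dir, decoyB_gene)
    )
    list(
      targets = targets, demis = demis, circ = circ,
      truth = list(
        pairs = tibble(mirna = planted_mi, mrna = mrna_names),
        circs = planted_circ,
        mrna_dirs = mrna_dirs,
        decoys = list(
          missing_source = tibble(mirna = decoyA_mi, mrna = decoyA_gene),
          same_direction = tibble(mirna = decoyB_mi, mrna = decoyB_gene),
          partial_coverage = decoy_circ
        )
      )
    )
  })
}
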