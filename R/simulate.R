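#' Configuration for the paired-study simulator
#'
#' Defines the data regime the analysis assumes: two replicated multi-day
#' log2-intensity time courses (an in vitro differentiation course and an in
#' vivo developmental course), a minority of miRNAs with single-day additive
#' expression peaks, repressive miRNA->target interactions producing
#' anti-correlated profiles that are planted in one or both studies, decoy
#' interactions, and several partially overlapping interaction resources.
#'
#' Defaults emulate the study design of a murine embryoid-body
#' differentiation course (days 0-16, three replicates, RMA-like log2
#' intensities roughly between 3 and 12) paired with a fetal heart
#' development course on its own embryonic-day grid.
#'
#' @param n_genes,n_mirnas Number of gene and miRNA features.
#' @param days_vitro,days_vivo Strictly increasing day labels (>= 3 each).
#' @param n_replicates Replicates per day (shared by both studies).
#' @param baseline_range Interval the flat per-feature baseline is drawn
#'   from, log2 units.
#' @param noise_sd I.i.d. Gaussian noise added per sample, log2 units.
#' @param peak_amplitude Log2 units added at a peaked miRNA's single peak
#'   day; also the ramp height of regulatorily active miRNAs.
#' @param frac_peaked_mirnas Fraction of miRNAs planted with a peak at each
#'   day (so `length(days) * frac` of miRNAs are peaked overall).
#' @param n_true_interactions Number of planted repressive miRNA->gene pairs.
#' @param frac_conserved Fraction of true interactions planted identically
#'   in both studies (the rest are planted in one study only).
#' @param repression_beta Unitless slope: target day-mean decrease per unit
#'   of miRNA day-mean excess over its own mean.
#' @param n_decoy_interactions Number of decoy miRNA->gene pairs. Decoy
#'   genes are drawn from genes not involved in any true interaction, so
#'   decoys are guaranteed true negatives for precision accounting.
#' @param n_resources Number of interaction-prediction resources.
#' @param resource_coverage Probability a resource lists a given candidate
#'   interaction.
#' @param seed Integer seed; identical configs give identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 600,
                              n_mirnas = 150,
                              days_vitro = c(0, 4, 8, 12, 16),
                              days_vivo = c(10.5, 12.5, 14.5, 16.5, 18.5),
                              n_replicates = 3,
                              baseline_range = c(3, 12),
                              noise_sd = 0.3,
                              peak_amplitude = 4,
                              frac_peaked_mirnas = 0.06,
                              n_true_interactions = 50,
                              frac_conserved = 0.8,
                              repression_beta = 1,
                              n_decoy_interactions = 500,
                              n_resources = 5,
                              resource_coverage = 0.8,
                              seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_mirnas = n_mirnas,
    days_vitro = days_vitro, days_vivo = days_vivo,
    n_replicates = n_replicates, baseline_range = baseline_range,
    noise_sd = noise_sd, peak_amplitude = peak_amplitude,
    frac_peaked_mirnas = frac_peaked_mirnas,
    n_true_interactions = n_true_interactions,
    frac_conserved = frac_conserved, repression_beta = repression_beta,
    n_decoy_interactions = n_decoy_interactions,
    n_resources = n_resources, resource_coverage = resource_coverage,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("Invalid simulation config: `%s` %s.", field, why))
  }
  counts <- c(
    "n_genes", "n_mirnas", "n_replicates", "n_true_interactions",
    "n_decoy_interactions", "n_resources"
  )
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      bad(f, "must be a non-negative integer")
    }
  }
  if (cfg$n_replicates < 1) bad("n_replicates", "must be >= 1")
  for (f in c("frac_peaked_mirnas", "frac_conserved", "resource_coverage")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad(f, "must lie in [0, 1]")
    }
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (length(cfg$baseline_range) != 2 ||
    cfg$baseline_range[1] >= cfg$baseline_range[2]) {
    bad("baseline_range", "must be an interval with lower < upper")
  }
  for (f in c("days_vitro", "days_vivo")) {
    d <- cfg[[f]]
    if (length(d) < 3 || any(diff(d) <= 0)) {
      bad(f, "must be strictly increasing with length >= 3")
    }
  }
  if (!is.numeric(cfg$repression_beta)) bad("repression_beta", "must be numeric")
  invisible(cfg)
}

# One study's matrix from deterministic day-mean profiles + iid noise.
# profiles: features x n_days matrix of noiseless day means.
build_study <- function(profiles, days, n_replicates, noise_sd, prefix) {
  n_feat <- nrow(profiles)
  samples <- tidyr::expand_grid(day = days, replicate = seq_len(n_replicates)) %>%
    dplyr::mutate(sample_id = sprintf("%s_d%g_r%d", prefix, .data$day, .data$replicate)) %>%
    dplyr::select("sample_id", "day", "replicate")
  values <- profiles[, rep(seq_along(days), each = n_replicates), drop = FALSE]
  if (noise_sd > 0) {
    values <- values + stats::rnorm(length(values), sd = noise_sd)
  }
  colnames(values) <- samples$sample_id
  expr <- dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(profiles)),
    tibble::as_tibble(values)
  )
  list(expr = expr, samples = samples)
}

# Monotone ramp over day indices, direction +1/-1, centred on zero so a
# ramped feature's day means straddle its baseline (and its maximum stays
# above the detection floor for any baseline above the range minimum).
ramp_profile <- function(n_days, direction) {
  direction * (seq(0, 1, length.out = n_days) - 0.5)
}

#' Simulate a paired in vitro / in vivo expression study with planted truth
#'
#' Generates four wide expression tables (mRNA and miRNA for each study) and
#' a machine-readable truth set. Each feature receives a flat log2 baseline
#' drawn uniformly from `baseline_range`. Peaked miRNAs get
#' `peak_amplitude` added at exactly one day (the same day index in both
#' studies). miRNAs engaged in true interactions follow a monotone ramp of
#' height `peak_amplitude` (random direction, shared between studies), and
#' each true interaction's target day-mean profile in a study it is planted
#' in equals the target's baseline minus `repression_beta` times the miRNA's
#' centred day-mean profile. I.i.d. Gaussian noise (sd `noise_sd`) is then
#' added per sample, so repression acts on profiles and replicate scatter
#' comes on top.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_study_pair` with elements `vitro_mrna`,
#'   `vitro_mirna`, `vivo_mrna`, `vivo_mirna` (each `list(expr, samples)`),
#'   `truth` and `config`. `truth` holds `peaked_mirnas` (tibble: mirna_id,
#'   peak_index, peak_day_vitro, peak_day_vivo), `true_interactions`
#'   (tibble: mirna_id, gene_id, membership in vitro/vivo/both),
#'   `decoy_interactions` (tibble: mirna_id, gene_id), `cardiac_genes`,
#'   `regulator_genes`, and the full `genes`/`mirnas` id vectors.
#' @export
simulate_study_pair <- function(config) {
  validate_simulation_config(config)
  withr::with_seed(config$seed, simulate_study_pair_impl(config))
}

simulate_study_pair_impl <- function(cfg) {
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  nd_vitro <- length(cfg$days_vitro)
  nd_vivo <- length(cfg$days_vivo)

  # -- planted peaks: same day index in both studies, disjoint day groups
  n_peak_per_day <- round(cfg$frac_peaked_mirnas * cfg$n_mirnas)
  n_peaked <- min(n_peak_per_day * nd_vitro, cfg$n_mirnas)
  peaked_ids <- if (n_peaked > 0) sample(mirnas, n_peaked) else character()
  peak_index <- rep(seq_len(nd_vitro), length.out = n_peaked)
  peaked <- tibble::tibble(
    mirna_id = peaked_ids,
    peak_index = peak_index,
    peak_day_vitro = cfg$days_vitro[peak_index],
    peak_day_vivo = cfg$days_vivo[pmin(peak_index, nd_vivo)]
  ) %>% dplyr::arrange(.data$mirna_id)

  # -- true interactions: ramped miRNAs repress distinct target genes
  free_mirnas <- setdiff(mirnas, peaked_ids)
  if (cfg$n_true_interactions > 0 && length(free_mirnas) == 0) {
    abort("Invalid simulation config: no miRNAs left for interactions.")
  }
  if (cfg$n_true_interactions > cfg$n_genes) {
    abort("Invalid simulation config: `n_true_interactions` exceeds `n_genes`.")
  }
  target_genes <- if (cfg$n_true_interactions > 0) {
    sample(genes, cfg$n_true_interactions)
  } else {
    character()
  }
  int_mirnas <- if (cfg$n_true_interactions > 0) {
    sample(free_mirnas, cfg$n_true_interactions, replace = TRUE)
  } else {
    character()
  }
  membership <- if (cfg$n_true_interactions > 0) {
    ifelse(
      stats::runif(cfg$n_true_interactions) < cfg$frac_conserved, "both",
      sample(c("vitro", "vivo"), cfg$n_true_interactions, replace = TRUE)
    )
  } else {
    character()
  }
  true_int <- tibble::tibble(
    mirna_id = int_mirnas, gene_id = target_genes, membership = membership
  ) %>% dplyr::arrange(.data$mirna_id, .data$gene_id)

  # -- decoys: random pairs whose gene is untargeted (guaranteed negatives)
  decoy_gene_pool <- setdiff(genes, target_genes)
  decoy <- tibble::tibble(mirna_id = character(), gene_id = character())
  if (cfg$n_decoy_interactions > 0) {
    n_possible <- length(decoy_gene_pool) * cfg$n_mirnas
    if (cfg$n_decoy_interactions > n_possible) {
      abort("Invalid simulation config: `n_decoy_interactions` exceeds available pairs.")
    }
    idx <- sample(n_possible, cfg$n_decoy_interactions)
    decoy <- tibble::tibble(
      mirna_id = mirnas[(idx - 1) %% cfg$n_mirnas + 1],
      gene_id = decoy_gene_pool[(idx - 1) %/% cfg$n_mirnas + 1]
    ) %>% dplyr::arrange(.data$mirna_id, .data$gene_id)
  }

  # -- annotation side of the truth: heart-like gene set, regulators
  other_genes <- setdiff(genes, target_genes)
  cardiac <- sort(c(
    target_genes,
    sample(other_genes, round(0.10 * length(other_genes)))
  ))
  regulators <- sort(sample(genes, round(0.15 * cfg$n_genes)))

  # -- deterministic day-mean profiles
  base_g <- stats::runif(cfg$n_genes, cfg$baseline_range[1], cfg$baseline_range[2])
  base_m <- stats::runif(cfg$n_mirnas, cfg$baseline_range[1], cfg$baseline_range[2])
  names(base_g) <- genes
  names(base_m) <- mirnas
  ramp_dir <- sample(c(-1, 1), cfg$n_mirnas, replace = TRUE)
  names(ramp_dir) <- mirnas

  mirna_profiles <- function(days) {
    nd <- length(days)
    prof <- matrix(base_m, nrow = cfg$n_mirnas, ncol = nd,
      dimnames = list(mirnas, NULL)
    )
    ramped <- unique(true_int$mirna_id)
    for (m in ramped) {
      prof[m, ] <- base_m[m] + cfg$peak_amplitude * ramp_profile(nd, ramp_dir[m])
    }
    if (nrow(peaked) > 0) {
      idx <- cbind(match(peaked$mirna_id, mirnas), pmin(peaked$peak_index, nd))
      prof[idx] <- prof[idx] + cfg$peak_amplitude
    }
    prof
  }

  gene_profiles <- function(mir_prof, study) {
    nd <- ncol(mir_prof)
    prof <- matrix(base_g, nrow = cfg$n_genes, ncol = nd,
      dimnames = list(genes, NULL)
    )
    planted <- true_int[true_int$membership %in% c("both", study), ]
    for (i in seq_len(nrow(planted))) {
      mp <- mir_prof[planted$mirna_id[i], ]
      prof[planted$gene_id[i], ] <-
        base_g[planted$gene_id[i]] - cfg$repression_beta * (mp - mean(mp))
    }
    prof
  }

  mir_vitro <- mirna_profiles(cfg$days_vitro)
  mir_vivo <- mirna_profiles(cfg$days_vivo)
  gene_vitro <- gene_profiles(mir_vitro, "vitro")
  gene_vivo <- gene_profiles(mir_vivo, "vivo")

  out <- list(
    vitro_mrna = build_study(gene_vitro, cfg$days_vitro, cfg$n_replicates,
      cfg$noise_sd, "vitro"),
    vitro_mirna = build_study(mir_vitro, cfg$days_vitro, cfg$n_replicates,
      cfg$noise_sd, "vitro"),
    vivo_mrna = build_study(gene_vivo, cfg$days_vivo, cfg$n_replicates,
      cfg$noise_sd, "vivo"),
    vivo_mirna = build_study(mir_vivo, cfg$days_vivo, cfg$n_replicates,
      cfg$noise_sd, "vivo"),
    truth = list(
      peaked_mirnas = peaked,
      true_interactions = true_int,
      decoy_interactions = decoy,
      cardiac_genes = cardiac,
      regulator_genes = regulators,
      genes = genes,
      mirnas = mirnas
    ),
    config = cfg
  )
  structure(out, class = "sim_study_pair")
}

#' Simulate partially overlapping interaction-prediction resources
#'
#' Each resource independently lists each candidate interaction (true or
#' decoy) with probability `resource_coverage`. The last resource is marked
#' as experimental evidence, the others as computational predictions,
#' mirroring a merge of four prediction databases with one curated resource.
#'
#' @param truth The `truth` element of a [simulate_study_pair()] result.
#' @param config The same [simulation_config()].
#' @return A list of `n_resources` tibbles with columns `mirna_id`,
#'   `gene_id`, `score`, `evidence`, `resource`.
#' @export
simulate_resources <- function(truth, config) {
  validate_simulation_config(config)
  candidates <- dplyr::bind_rows(
    dplyr::select(truth$true_interactions, "mirna_id", "gene_id"),
    truth$decoy_interactions
  ) %>% dplyr::arrange(.data$mirna_id, .data$gene_id)
  withr::with_seed(config$seed + 1000L, {
    purrr::map(seq_len(config$n_resources), function(i) {
      keep <- stats::runif(nrow(candidates)) < config$resource_coverage
      candidates[keep, ] %>%
        dplyr::mutate(
          score = round(stats::runif(sum(keep)), 3),
          evidence = if (i == config$n_resources) "experimental" else "predicted",
          resource = sprintf("resource%d", i)
        )
    })
  })
}

#' Simulate a toy ontology DAG with a planted heart-development-like term
#'
#' Builds a single-rooted acyclic term graph: one designated term
#' (`term_heart`) directly annotating exactly `truth$cardiac_genes`, plus
#' `n_filler_terms` terms annotating random gene subsets. Fillers attach to
#' the root or to an earlier filler; every fifth filler gets a second parent
#' so multi-parent propagation is exercised.
#'
#' @param truth The `truth` element of a [simulate_study_pair()] result.
#' @param n_filler_terms Number of random terms besides root and heart term.
#' @param seed Integer seed.
#' @return An [ontology_dag()] (not yet propagated).
#' @export
simulate_ontology <- function(truth, n_filler_terms = 30, seed = 1L) {
  withr::with_seed(as.integer(seed) + 2000L, {
    terms <- c("term_root", "term_heart")
    edges <- tibble::tibble(child = "term_heart", parent = "term_root")
    ann <- tibble::tibble(
      gene_id = truth$cardiac_genes, term_id = "term_heart"
    )
    for (i in seq_len(n_filler_terms)) {
      id <- sprintf("term_f%03d", i)
      parents <- if (i == 1) "term_root" else sample(terms[-2], 1)
      if (i %% 5 == 0 && i > 5) {
        second <- sample(setdiff(terms[-2], parents), 1)
        parents <- c(parents, second)
      }
      edges <- dplyr::bind_rows(
        edges, tibble::tibble(child = id, parent = parents)
      )
      size <- sample(5:40, 1)
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        gene_id = sample(truth$genes, min(size, length(truth$genes))),
        term_id = id
      ))
      terms <- c(terms, id)
    }
    ontology_dag(edges, ann)
  })
}

#' Write a simulated fixture set as plain-text files
#'
#' Emits expression and sample-sheet TSVs for the four studies, one
#' interaction TSV per resource, ontology edge and annotation TSVs, the
#' regulator-gene list (one id per line), and the planted truth as JSON.
#'
#' @param sim A [simulate_study_pair()] result.
#' @param resources Output of [simulate_resources()].
#' @param ontology An [ontology_dag()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of written paths.
#' @export
write_fixture_set <- function(sim, resources, ontology, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in c("vitro_mrna", "vitro_mirna", "vivo_mrna", "vivo_mirna")) {
    ep <- file.path(dir, paste0(nm, "_expr.tsv"))
    sp <- file.path(dir, paste0(nm, "_samples.tsv"))
    readr::write_tsv(sim[[nm]]$expr, ep)
    readr::write_tsv(sim[[nm]]$samples, sp)
    paths[[paste0(nm, "_expr")]] <- ep
    paths[[paste0(nm, "_samples")]] <- sp
  }
  for (tab in resources) {
    rp <- file.path(dir, paste0(tab$resource[1], ".tsv"))
    readr::write_tsv(tab, rp)
    paths[[tab$resource[1]]] <- rp
  }
  readr::write_tsv(ontology$edges, file.path(dir, "ontology_edges.tsv"))
  readr::write_tsv(ontology$annotations, file.path(dir, "ontology_annotations.tsv"))
  writeLines(sim$truth$regulator_genes, file.path(dir, "regulator_genes.txt"))
  jsonlite::write_json(
    list(
      peaked_mirnas = sim$truth$peaked_mirnas,
      true_interactions = sim$truth$true_interactions,
      decoy_interactions = sim$truth$decoy_interactions,
      cardiac_genes = sim$truth$cardiac_genes,
      regulator_genes = sim$truth$regulator_genes
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", pretty = TRUE
  )
  paths$ontology_edges <- file.path(dir, "ontology_edges.tsv")
  paths$ontology_annotations <- file.path(dir, "ontology_annotations.tsv")
  paths$regulator_genes <- file.path(dir, "regulator_genes.txt")
  paths$truth <- file.path(dir, "truth.json")
  invisible(paths)
}
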