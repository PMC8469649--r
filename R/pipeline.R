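#' Assemble a pipeline configuration
#'
#' A configuration has three blocks: `simulate` (a [simulation_config()]
#' used when no input files are given), `inputs` (paths to expression,
#' sample-sheet, interaction, ontology, gene-set and regulator files) and
#' `thresholds`. Threshold defaults are the analysis defaults throughout
#' the package: expression floor 5 (log2), DE at adjusted p < 1e-5 and
#' |log2FC| > 2 (strict), peak calls at r >= 0.6 on day-mean profiles,
#' anti-correlation at tau < -0.2, conservation at |delta tau| < 0.2,
#' top 10 peak miRNAs per day, child-term conditioning at p <= 0.01.
#'
#' @param simulate A [simulation_config()] (or `NULL` when `inputs` given).
#' @param inputs Named list of file paths (see [run_pipeline()]), or `NULL`.
#' @param thresholds Named list overriding individual threshold defaults.
#' @param out_dir Directory for stage outputs, or `NULL` to keep results in
#'   memory only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(), inputs = NULL,
                            thresholds = list(), out_dir = NULL) {
  defaults <- list(
    expression_floor = 5,
    de_alpha = 1e-5,
    de_lfc = 2,
    de_strict = TRUE,
    peak_r_min = 0.6,
    peak_level = "day_mean",
    top_k_per_day = 10,
    anticorr_tau = -0.2,
    conservation_delta = 0.2,
    conservation_strict = TRUE,
    enrichment_child_alpha = 0.01
  )
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown threshold(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(thresholds)] <- thresholds
  stopifnot(
    defaults$de_alpha > 0, defaults$de_alpha < 1,
    abs(defaults$peak_r_min) <= 1, abs(defaults$anticorr_tau) <= 1,
    defaults$conservation_delta >= 0,
    defaults$peak_level %in% c("day_mean", "replicate")
  )
  structure(
    list(simulate = simulate, inputs = inputs, thresholds = defaults,
      out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File with blocks `simulate`, `inputs`, `thresholds`,
#'   `out_dir`.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim <- if (is.null(raw$inputs)) {
    do.call(simulation_config, raw$simulate %||% list())
  } else {
    NULL
  }
  pipeline_config(
    simulate = sim,
    inputs = raw$inputs,
    thresholds = raw$thresholds %||% list(),
    out_dir = raw$out_dir
  )
}

load_study <- function(inputs, name) {
  list(
    expr = read_expression_tsv(inputs[[paste0(name, "_expr")]]),
    samples = read_sample_sheet(inputs[[paste0(name, "_samples")]])
  )
}

stage_error <- function(stage, msg) {
  abort(sprintf("Pipeline stage `%s` failed: %s", stage, msg))
}

#' Run the full integrative analysis end to end
#'
#' Executes, in order: expression filtering for the four studies
#' (in vitro / in vivo, mRNA / miRNA); differential expression of the in
#' vitro studies against day zero; one-hot peak calling on the in vitro
#' miRNAs with per-day top-k selection; merging of the interaction
#' resources and per-study restriction to expressed partners; Kendall
#' correlation annotation in each study; cross-study overlap, gene-set
#' restriction and conserved-interaction selection; miRNA ranking; and
#' conditioned ontology enrichment of the per-day anti-correlated targets
#' of the top peak miRNAs. All randomness derives from the simulation
#' seed, so identical configurations reproduce identical outputs; when
#' `out_dir` is set, every stage writes a TSV and the manifest is written
#' as JSON.
#'
#' When `config$inputs` is `NULL`, fixtures are generated in memory from
#' `config$simulate`. Otherwise `inputs` must name the files:
#' `vitro_mrna_expr`/`_samples`, `vitro_mirna_expr`/`_samples`,
#' `vivo_mrna_expr`/`_samples`, `vivo_mirna_expr`/`_samples`, `resources`
#' (vector of interaction TSVs), `ontology_edges`, `ontology_annotations`,
#' `gene_set` (one gene id per line) and optionally `regulator_genes`.
#'
#' @param config A [pipeline_config()], or a YAML/JSON path.
#' @param out_dir Overrides `config$out_dir`.
#' @return A list of class `run_manifest` with `counts` (stage record
#'   counts), `thresholds`, `input_digests`, `outputs` (written paths) and
#'   `results` (the in-memory stage tables).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config or a path to one.")
  }
  th <- config$thresholds
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(name, ".tsv"))
      flat <- tbl
      for (col in names(flat)) {
        if (is.list(flat[[col]])) {
          flat[[col]] <- purrr::map_chr(flat[[col]], paste, collapse = ",")
        }
      }
      readr::write_tsv(tibble::as_tibble(flat), path)
      outputs[[name]] <<- path
    }
    invisible(tbl)
  }

  # ---- load or simulate inputs -------------------------------------------
  digests <- list()
  if (is.null(config$inputs)) {
    if (is.null(config$simulate)) {
      stage_error("inputs", "neither input files nor a simulation block given")
    }
    sim <- simulate_study_pair(config$simulate)
    resources <- simulate_resources(sim$truth, config$simulate)
    ontology <- simulate_ontology(sim$truth, seed = config$simulate$seed)
    gene_set <- sim$truth$cardiac_genes
    regulators <- sim$truth$regulator_genes
    studies <- sim[c("vitro_mrna", "vitro_mirna", "vivo_mrna", "vivo_mirna")]
    digests$simulation_seed <- config$simulate$seed
  } else {
    inp <- config$inputs
    need <- c(
      "vitro_mrna_expr", "vitro_mrna_samples", "vitro_mirna_expr",
      "vitro_mirna_samples", "vivo_mrna_expr", "vivo_mrna_samples",
      "vivo_mirna_expr", "vivo_mirna_samples"
    )
    missing <- setdiff(need, names(inp))
    if (length(missing) > 0) {
      stage_error("inputs", paste("missing:", paste(missing, collapse = ", ")))
    }
    files <- unlist(inp[c(need, "resources", "ontology_edges",
      "ontology_annotations", "gene_set", "regulator_genes")], use.names = FALSE)
    files <- files[!is.na(files) & nzchar(files)]
    absent <- files[!file.exists(files)]
    if (length(absent) > 0) {
      stage_error("inputs", paste("file not found:", paste(absent, collapse = ", ")))
    }
    digests <- as.list(stats::setNames(tools::md5sum(files), basename(files)))
    studies <- list(
      vitro_mrna = load_study(inp, "vitro_mrna"),
      vitro_mirna = load_study(inp, "vitro_mirna"),
      vivo_mrna = load_study(inp, "vivo_mrna"),
      vivo_mirna = load_study(inp, "vivo_mirna")
    )
    resources <- purrr::map(inp$resources, read_interaction_tsv)
    ontology <- if (!is.null(inp$ontology_edges)) {
      ontology_dag(
        readr::read_tsv(inp$ontology_edges, show_col_types = FALSE),
        readr::read_tsv(inp$ontology_annotations, show_col_types = FALSE)
      )
    } else {
      NULL
    }
    gene_set <- if (!is.null(inp$gene_set)) readLines(inp$gene_set) else NULL
    regulators <- if (!is.null(inp$regulator_genes)) {
      readLines(inp$regulator_genes)
    } else {
      character()
    }
    sim <- NULL
  }

  counts <- list()

  # ---- stage: expression filtering ---------------------------------------
  expressed <- purrr::imap(studies, function(st, nm) {
    out <- filter_expressed(st$expr, st$samples, floor = th$expression_floor)
    emit(out, paste0("expressed_", nm))
    out
  })
  counts$expressed <- purrr::map_int(expressed, nrow)

  # ---- stage: differential expression (in vitro vs day 0) ----------------
  de <- purrr::map(c(vitro_mrna = "vitro_mrna", vitro_mirna = "vitro_mirna"),
    function(nm) {
      res <- diff_expression(
        expressed[[nm]], studies[[nm]]$samples,
        alpha = th$de_alpha, lfc_min = th$de_lfc, strict = th$de_strict
      )
      emit(res, paste0("de_", nm))
      res
    }
  )
  counts$de_per_day <- purrr::map(de, function(res) {
    res %>%
      dplyr::filter(.data$is_de) %>%
      dplyr::count(.data$day) %>%
      (function(x) stats::setNames(as.list(x$n), paste0("day_", x$day)))()
  })

  # ---- stage: peak calling (in vitro miRNAs) -----------------------------
  peak_input <- if (th$peak_level == "replicate") {
    expression_long(expressed$vitro_mirna, studies$vitro_mirna$samples)
  } else {
    day_mean_profiles(expressed$vitro_mirna, studies$vitro_mirna$samples)
  }
  peaks <- suppressWarnings(call_peaks(peak_input, r_min = th$peak_r_min))
  emit(peaks, "peaks_vitro")
  top_peaks <- top_k_by_day(peaks, k = th$top_k_per_day)
  emit(top_peaks, "peaks_top_per_day")
  counts$peaks_per_day <- as.list(table(peaks$peak_day))

  # ---- stage: interaction merging and correlation ------------------------
  if (length(resources) == 0) {
    stage_error("interactions", "no interaction resources configured; stopping after peaks")
  }
  merged <- merge_resources(resources)
  emit(merged, "merged_interactions")
  counts$merged <- nrow(merged)

  annotated <- purrr::map(c(vitro = "vitro", vivo = "vivo"), function(study) {
    mirna_nm <- paste0(study, "_mirna")
    mrna_nm <- paste0(study, "_mrna")
    restricted <- restrict_to_expressed(
      merged,
      expressed_mirnas = expressed[[mirna_nm]]$feature_id,
      expressed_genes = expressed[[mrna_nm]]$feature_id
    )
    ann <- annotate_correlations(
      restricted,
      day_mean_profiles(expressed[[mirna_nm]], studies[[mirna_nm]]$samples),
      day_mean_profiles(expressed[[mrna_nm]], studies[[mrna_nm]]$samples)
    )
    emit(ann, paste0("correlations_", study))
    ann
  })
  counts$correlated <- purrr::map_int(annotated, nrow)

  # ---- stage: cross-study conservation -----------------------------------
  overlap <- intersect_studies(annotated$vitro, annotated$vivo)
  emit(overlap, "overlap_interactions")
  counts$overlap <- nrow(overlap)

  in_set <- if (is.null(gene_set)) overlap else restrict_gene_set(overlap, gene_set)
  emit(in_set, "gene_set_interactions")
  counts$gene_set <- nrow(in_set)

  conserved <- select_conserved(in_set,
    delta_max = th$conservation_delta,
    tau_max = th$anticorr_tau,
    strict = th$conservation_strict
  )
  emit(conserved, "conserved_interactions")
  counts$conserved <- nrow(conserved)
  summary <- summarize_run(conserved)
  counts$conserved_unique_mirnas <- summary$n_unique_mirnas
  counts$conserved_unique_genes <- summary$n_unique_genes

  priority <- rank_mirnas(conserved, regulator_genes = regulators)
  emit(priority, "mirna_priority")

  # ---- stage: enrichment of per-day peak-miRNA targets -------------------
  enrichment <- NULL
  if (!is.null(ontology)) {
    ontology <- propagate_annotations(ontology)
    universe <- sort(unique(unlist(ontology$propagated)))
    anti_vitro <- filter_anticorrelated(annotated$vitro, tau_max = th$anticorr_tau)
    enrichment <- top_peaks %>%
      dplyr::distinct(.data$peak_day, .data$mirna_id) %>%
      dplyr::inner_join(anti_vitro, by = "mirna_id",
        relationship = "many-to-many") %>%
      dplyr::group_by(.data$peak_day) %>%
      dplyr::group_map(function(rows, key) {
        selected <- intersect(unique(rows$gene_id), universe)
        if (length(selected) == 0) return(NULL)
        conditional_enrichment(ontology, selected,
          universe = universe,
          child_alpha = th$enrichment_child_alpha
        ) %>% dplyr::mutate(peak_day = key$peak_day, .before = 1)
      }) %>%
      dplyr::bind_rows()
    class(enrichment) <- unique(c("enrichment_results", class(enrichment)))
    if (nrow(enrichment) > 0) emit(enrichment, "enrichment_by_day")
    counts$enrichment_tests <- nrow(enrichment)
  }

  manifest <- structure(
    list(
      thresholds = th,
      simulate = if (is.null(config$inputs)) unclass(config$simulate) else NULL,
      input_digests = digests,
      counts = counts,
      outputs = outputs,
      results = list(
        expressed = expressed, de = de, peaks = peaks, top_peaks = top_peaks,
        merged = merged, annotated = annotated, overlap = overlap,
        conserved = conserved, priority = priority, enrichment = enrichment,
        summary = summary, truth = if (is.null(sim)) NULL else sim$truth
      )
    ),
    class = "run_manifest"
  )
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, "manifest.json")
    serial <- manifest[c("thresholds", "simulate", "input_digests", "counts",
      "outputs")]
    # manifests of identical runs must be byte-identical wherever they live
    serial$outputs <- lapply(serial$outputs, basename)
    jsonlite::write_json(serial, path, auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    manifest$outputs$manifest <- path
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Integrative miRNA-mRNA pipeline run\n")
  cat(sprintf("  expressed features: %s\n",
    paste(sprintf("%s=%d", names(x$counts$expressed), x$counts$expressed),
      collapse = ", ")))
  cat(sprintf("  peak calls: %d\n", sum(unlist(x$counts$peaks_per_day))))
  cat(sprintf(
    "  interactions: merged %d -> overlap %d -> gene set %d -> conserved %d\n",
    x$counts$merged, x$counts$overlap, x$counts$gene_set, x$counts$conserved
  ))
  cat(sprintf("  conserved: %d pairs, %d miRNAs, %d genes\n",
    x$counts$conserved, x$counts$conserved_unique_mirnas,
    x$counts$conserved_unique_genes))
  invisible(x)
}
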