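# End-to-end orchestration: one config drives copy-number estimation, group
# statistics, PGLS association, family characterization and the expression
# report, writing TSV outputs plus a manifest with parameters and input
# checksums.

default_config <- function() {
  list(
    out_dir = "cnvchemo_run",
    seed = 1,
    stages = c("simulate", "cn", "stats", "pgls", "family", "expression"),
    paths = list(),           # depth, regions, samples, tree, chemotype,
                              # fasta, counts, library_sizes
    parameters = list(
      genome_size = 818e6,    # female default; 843e6 for male libraries
      decarb_factor = 0.877,
      posthoc = "tukey",
      pseudocount = 0.1,
      cannabinoids = c("THC", "CBD", "CBC", "total"),
      distance_model = "p"
    )
  )
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  cfg$stages <- intersect(c("simulate", "cn", "stats", "pgls", "family", "expression"),
                          cfg$stages)
  cfg
}

validate_run_config <- function(cfg) {
  simulate <- "simulate" %in% cfg$stages
  need <- character(0)
  if (!simulate) {
    if ("cn" %in% cfg$stages) need <- c(need, "depth", "regions", "samples")
    if ("pgls" %in% cfg$stages) need <- c(need, "tree", "chemotype")
    if ("family" %in% cfg$stages) need <- c(need, "fasta")
    if ("expression" %in% cfg$stages) need <- c(need, "counts", "library_sizes")
  } else if ("family" %in% cfg$stages && !is.null(cfg$paths$fasta)) {
    need <- c(need, "fasta")
  }
  missing <- setdiff(unique(need), names(cfg$paths))
  if (length(missing) > 0) {
    stop_config(sprintf("config enables stages that need input path(s): %s",
                        paste(missing, collapse = ", ")))
  }
  gone <- unlist(cfg$paths[unique(need)]) %||% character(0)
  gone <- gone[!file.exists(gone)]
  if (length(gone) > 0) {
    stop_config(sprintf("input file(s) do not exist: %s", paste(gone, collapse = ", ")))
  }
  invisible(cfg)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[cnvchemo] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — synthetic-data generation (or
#' ingestion of user inputs), copy-number estimation, lineage/cultivar
#' statistics, PGLS chemotype association, paralog-family sequence
#' characterization, and the expression report — writing each stage's TSV
#' outputs and a run manifest (parameters, input checksums) under
#' `out_dir`. The run is deterministic given the config and seed; a stage
#' failure aborts with the failing stage named and leaves a `FAILED` marker
#' alongside any partial outputs.
#'
#' @param config A config list or path to a YAML config. Recognized fields:
#'   `out_dir`, `seed`, `stages` (subset of simulate/cn/stats/pgls/family/
#'   expression), `paths` (named input paths: depth, regions, samples,
#'   tree, chemotype, fasta, counts, library_sizes), and `parameters`
#'   (genome_size, decarb_factor, pseudocount, cannabinoids,
#'   distance_model).
#' @return Invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_run_config(config)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  emit <- function(df, name) {
    readr::write_tsv(tibble::as_tibble(df), file.path(cfg$out_dir, name))
  }

  run_stage <- function(stage, expr) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    pipeline_log("stage '%s' started", stage)
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)),
                   class = c("cnvchemo_stage_error", "cnvchemo_error"))
    })
  }

  # --- inputs -------------------------------------------------------------
  inputs <- list()
  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", {
      cohort <- simulate_cohort(seed = cfg$seed,
                                genome_size = cfg$parameters$genome_size)
      tt <- simulate_tree_and_traits(n_tips = nrow(cohort$samples),
                                     seed = cfg$seed)
      tt$tree$tip.label <- cohort$samples$sample_id
      chem <- tibble::tibble(
        cultivar = cohort$samples$cultivar,
        sample_id = cohort$samples$sample_id,
        cannabinoid = "THC",
        percent = pmax(tt$traits$y - min(tt$traits$y), 0),
        provenance = "individual"
      )
      expr_sim <- simulate_expression(seed = cfg$seed)
      inputs <- list(depths = cohort$depths, regions = cohort$regions,
                      samples = cohort$samples, tree = tt$tree,
                      chemotype = chem, counts = expr_sim$counts,
                      library_sizes = expr_sim$library_sizes)
      emit(cohort$truth, "synthetic_truth_cn.tsv")
      pipeline_log("simulated %d samples x %d regions",
                   nrow(cohort$samples), nrow(cohort$regions))
      results$synthetic <- cohort
    })
  } else {
    p <- cfg$paths
    if (!is.null(p$depth)) {
      inputs$depths <- read_depth_tsv(p$depth)
      if (!"sample_id" %in% names(inputs$depths)) {
        stop_config("multi-sample depth input must carry a sample_id column")
      }
    }
    if (!is.null(p$regions)) inputs$regions <- read_regions_bed(p$regions)
    if (!is.null(p$samples)) inputs$samples <- read_sample_sheet(p$samples)
    if (!is.null(p$tree)) inputs$tree <- ape::read.tree(p$tree)
    if (!is.null(p$chemotype)) inputs$chemotype <- read_chemotype_tsv(p$chemotype)
    if (!is.null(p$counts)) {
      inputs$counts <- readr::read_tsv(p$counts, col_types = readr::cols(),
                                       progress = FALSE)
    }
    if (!is.null(p$library_sizes)) {
      ls <- readr::read_tsv(p$library_sizes, col_types = readr::cols(),
                            progress = FALSE)
      inputs$library_sizes <- setNames(ls$library_size, ls$condition)
    }
  }
  if (!is.null(cfg$paths$fasta)) inputs$fasta <- read_coding_fasta(cfg$paths$fasta)

  # --- stages -------------------------------------------------------------
  run_stage("cn", {
    cn <- estimate_cn_table(inputs$depths, inputs$regions, inputs$samples)
    emit(cn, "cn_table.tsv")
    pipeline_log("cn: %d samples, %d paralogs", nrow(cn),
                 ncol(cn) - 3L)
    results$cn_table <- cn
  })

  run_stage("stats", {
    st <- cn_lineage_stats(results$cn_table)
    emit(st$anova, "anova_lineage.tsv")
    emit(st$posthoc, "posthoc_lineage.tsv")
    cult <- tryCatch(cn_cultivar_stats(results$cn_table),
                     error = function(e) tibble::tibble())
    if (nrow(cult) > 0) emit(cult, "cultivar_tests.tsv")
    pipeline_log("stats: %d paralog ANOVAs", nrow(st$anova))
    results$stats <- st
  })

  run_stage("pgls", {
    assoc <- purrr::map_dfr(cfg$parameters$cannabinoids, function(cb) {
      tryCatch(
        correlate_cn_chemotype(results$cn_table, inputs$chemotype,
                               inputs$tree, cb),
        cnvchemo_error = function(e) {
          pipeline_log("pgls: skipping %s (%s)", cb, conditionMessage(e))
          tibble::tibble()
        })
    })
    emit(assoc, "pgls_associations.tsv")
    pairs <- correlate_cn_pairs(results$cn_table, inputs$tree)
    emit(pairs, "pgls_cn_pairs.tsv")
    pipeline_log("pgls: %d paralog x cannabinoid fits on n = %s samples",
                 nrow(assoc), paste(unique(assoc$n), collapse = "/"))
    results$pgls <- list(chemotype = assoc, cn_pairs = pairs)
  })

  run_stage("family", {
    seqs <- inputs$fasta
    if (is.null(seqs)) {
      sim <- simulate_codon_pair(n_codons = 300, n_substitutions = 30,
                                 omega = 0.5, seed = cfg$seed)
      seqs <- c(ancestor = sim$ancestor, derived = sim$derived)
    }
    fam <- pairwise_family_table(seqs)
    emit(fam, "family_pairwise.tsv")
    trunc <- truncation_report(seqs)
    emit(trunc, "truncation_report.tsv")
    if (length(seqs) >= 3) {
      d <- distance_matrix(seqs, model = cfg$parameters$distance_model)
      ape::write.tree(nj_tree(d), file.path(cfg$out_dir, "nj_tree.nwk"))
    }
    pipeline_log("family: %d sequences, %d pairs, %d truncated",
                 length(seqs), nrow(fam), sum(trunc$is_truncated))
    results$family <- list(pairwise = fam, truncation = trunc)
  })

  run_stage("expression", {
    rep <- expression_report(inputs$counts, inputs$library_sizes,
                             pseudocount = cfg$parameters$pseudocount)
    emit(rep, "expression_report.tsv")
    pipeline_log("expression: %d transcripts", nrow(rep))
    results$expression <- rep
  })

  # --- manifest -----------------------------------------------------------
  in_paths <- unlist(cfg$paths)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cnvchemo")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg$parameters,
    input_checksums = if (length(in_paths)) {
      as.list(tools::md5sum(in_paths[file.exists(in_paths)]))
    } else list()
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipeline_log("run complete: %s", cfg$out_dir)
  invisible(results)
}
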