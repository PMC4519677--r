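#' Assemble a pipeline run configuration
#'
#' A `RunConfig` is a plain named list; this helper fills defaults and
#' validates it. Input can come from a simulation block (`simulate`) or
#' from files (`input$fasta` + `input$species_map`, optionally
#' `input$fastq` for the QC stage or `input$aligned = TRUE` to bypass the
#' aligner). A single seed governs every stochastic stage and is recorded
#' in the output manifest.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed for all stochastic stages.
#' @param stages Character vector of stages to run, in canonical order
#'   among: simulate, qc, align, dist, gap, tree, design, multiplex, ipcr.
#' @param simulate `SimParams` (or list of arguments for [sim_params()]),
#'   or NULL when reading files.
#' @param input List: `fasta`, `species_map`, optional `fastq`, `qual`,
#'   `aligned` (logical).
#' @param qc,align,dist,tree,design,multiplex,ipcr Per-stage parameter
#'   blocks (see each module's parameter constructor).
#' @param force Rerun stages whose outputs already exist.
#' @return List of class `RunConfig`.
#' @export
run_config <- function(outdir, seed = 1L,
                       stages = c("simulate", "qc", "align", "dist", "gap",
                                  "tree", "design", "multiplex", "ipcr"),
                       simulate = NULL, input = NULL,
                       qc = qc_params(), align = align_params(),
                       dist = list(model = "K2P"),
                       tree = list(replicates = 1000L),
                       design = design_constraints(),
                       multiplex = list(min_separation = 30L),
                       ipcr = pcr_params(), force = FALSE) {
  if (is.null(simulate) && is.null(input)) {
    stop("config needs either a 'simulate' block or an 'input' block")
  }
  if (!is.null(input)) {
    input <- input[!vapply(input, is.null, logical(1))]
    for (f in intersect(c("fasta", "fastq", "qual", "species_map"),
                        names(input))) {
      if (!file.exists(input[[f]])) stop("input path missing: ", input[[f]])
    }
  }
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 simulate = simulate, input = input, qc = qc, align = align,
                 dist = dist, tree = tree, design = design,
                 multiplex = multiplex, ipcr = ipcr, force = force),
            class = "RunConfig")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) raw$simulate <- do.call(sim_params, raw$simulate)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

manifest_entry <- function(stage, inputs, outputs, params) {
  list(stage = stage, inputs = inputs, outputs = as.list(outputs),
       checksums = as.list(tools::md5sum(unlist(outputs))),
       params = params, status = "complete")
}

#' Run the full barcoding/marker pipeline
#'
#' Executes the configured stages in order (simulate or read inputs, QC,
#' align, distances, barcoding gap, NJ tree with bootstrap, marker
#' design, multiplex grouping, in-silico PCR validation), writing every
#' artifact under `config$outdir` and a JSON manifest recording the
#' configuration, seed, per-stage inputs/outputs/parameters and output
#' checksums. A stage already marked complete in an existing manifest
#' whose outputs still match their checksums is skipped unless
#' `config$force` is TRUE; a stage failure aborts with the stage name.
#'
#' @param config A `RunConfig`.
#' @return The manifest (invisibly also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  old <- if (file.exists(manifest_path) && !cfg$force) {
    jsonlite::read_json(manifest_path)
  } else NULL
  manifest <- list(seed = cfg$seed, stages = list())
  state <- new.env(parent = emptyenv())

  done_before <- function(stage) {
    if (is.null(old)) return(FALSE)
    e <- old$stages[[stage]]
    if (is.null(e) || !identical(e$status, "complete")) return(FALSE)
    outs <- unlist(e$outputs)
    all(file.exists(outs)) &&
      identical(as.list(tools::md5sum(outs)), e$checksums)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    entry <- tryCatch(fun(reuse = done_before(stage)),
                      error = function(e) {
                        stop("pipeline stage '", stage, "' failed: ",
                             conditionMessage(e), call. = FALSE)
                      })
    manifest$stages[[stage]] <<- entry
  }
  path <- function(...) file.path(cfg$outdir, ...)

  run_stage("simulate", function(reuse) {
    sim <- simulate_species_set(cfg$simulate)
    write_fasta(sim$sequences, path("simulated.fasta"))
    utils::write.table(sim$species_map, path("species_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sim$registry, path("planted_sites.json"))
    write_newick(sim$tree, path("true_tree.nwk"))
    state$seqs <- sim$sequences
    state$species <- species_lookup(sim$species_map)
    state$sim <- sim
    manifest_entry("simulate", list(),
                   c(path("simulated.fasta"), path("species_map.tsv"),
                     path("planted_sites.json"), path("true_tree.nwk")),
                   unclass(cfg$simulate))
  })
  if (is.null(cfg$simulate)) {
    state$species <- species_lookup(read_species_map(cfg$input$species_map))
    if (!is.null(cfg$input$fastq) || !is.null(cfg$input$qual)) {
      run_stage("qc", function(reuse) {
        qseqs <- if (!is.null(cfg$input$fastq)) {
          read_quality(cfg$input$fastq)
        } else read_quality(cfg$input$fasta, cfg$input$qual)
        rep <- qc_report(qseqs, cfg$qc)
        utils::write.table(rep, path("qc_report.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        acc <- qc_accepted(qseqs, cfg$qc)
        write_fasta(acc, path("qc_accepted.fasta"))
        state$seqs <- acc
        manifest_entry("qc",
                       list(fastq = cfg$input$fastq, qual = cfg$input$qual),
                       c(path("qc_report.tsv"), path("qc_accepted.fasta")),
                       unclass(cfg$qc))
      })
    }
    if (is.null(state$seqs)) state$seqs <- read_fasta(cfg$input$fasta)
  }

  run_stage("align", function(reuse) {
    pre <- !is.null(cfg$input) && isTRUE(cfg$input$aligned)
    aln <- if (pre) {
      labeled_alignment(state$seqs, state$species)
    } else {
      progressive_msa(state$seqs, cfg$align, species_of = state$species)
    }
    write_fasta(aln$rows, path("aligned.fasta"))
    state$aln <- aln
    manifest_entry("align", list(pre_aligned = pre),
                   path("aligned.fasta"), unclass(cfg$align))
  })
  needs_aln <- c("dist", "gap", "tree", "design", "multiplex", "ipcr")
  if (is.null(state$aln) && any(needs_aln %in% cfg$stages)) {
    state$aln <- labeled_alignment(state$seqs, state$species)
  }

  run_stage("dist", function(reuse) {
    dm <- distance_matrix(state$aln, model = cfg$dist$model)
    write_distance_tsv(dm, path("distances.tsv"))
    utils::write.table(pair_detail(state$aln), path("pair_detail.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$dm <- dm
    manifest_entry("dist", list(),
                   c(path("distances.tsv"), path("pair_detail.tsv")),
                   cfg$dist)
  })

  run_stage("gap", function(reuse) {
    gr <- gap_analysis(state$dm)
    write_gap_tsv(gr, path("gap_report.tsv"))
    state$gap <- gr
    manifest_entry("gap", list(), path("gap_report.tsv"), list())
  })

  run_stage("tree", function(reuse) {
    tr <- bootstrap_support(state$aln,
                            replicates = cfg$tree$replicates,
                            seed = cfg$seed)
    write_newick(tr, path("nj_tree.nwk"))
    mono <- species_monophyly_check(tr, state$aln$species_of)
    utils::write.table(
      data.frame(species = names(mono), monophyletic = mono),
      path("monophyly.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    state$tree <- tr
    manifest_entry("tree", list(replicates = cfg$tree$replicates),
                   c(path("nj_tree.nwk"), path("monophyly.tsv")),
                   cfg$tree)
  })

  run_stage("design", function(reuse) {
    targets <- unique(state$aln$species_of)
    markers <- list()
    for (sp in targets) {
      got <- design_primer_pairs(state$aln, sp, cfg$design)
      if (length(got)) markers[[sp]] <- got[[1]]
    }
    state$markers <- unname(markers)
    write_marker_report(state$markers, path("markers.tsv"))
    manifest_entry("design", list(targets = targets), path("markers.tsv"),
                   unclass(cfg$design)[c("primer_len_min", "primer_len_max",
                                         "tm_min", "tm_max", "delta_tm_max",
                                         "product_min", "product_max")])
  })

  run_stage("multiplex", function(reuse) {
    mg <- build_multiplex_groups(state$markers,
                                 min_separation = cfg$multiplex$min_separation)
    rows <- do.call(rbind, lapply(seq_along(mg$groups), function(i) {
      g <- mg$groups[[i]]
      data.frame(group = i, annealing_temp = g$annealing_temp,
                 members = paste(g$members, collapse = ","),
                 sizes = paste(g$sizes, collapse = ","),
                 min_size_separation = g$min_size_separation)
    }))
    if (is.null(rows)) rows <- data.frame(group = integer(0))
    utils::write.table(rows, path("multiplex_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    state$multiplex <- mg
    manifest_entry("multiplex", list(), path("multiplex_groups.tsv"),
                   cfg$multiplex)
  })

  run_stage("ipcr", function(reuse) {
    templates <- unlist(degap_rows(state$aln$rows))
    smat <- specificity_matrix(state$markers, templates,
                               state$aln$species_of, cfg$ipcr)
    write_specificity_tsv(smat, path("specificity_matrix.tsv"))
    state$smat <- smat
    manifest_entry("ipcr", list(), path("specificity_matrix.tsv"),
                   unclass(cfg$ipcr))
  })

  manifest$config <- serializable_config(cfg)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  state$manifest <- manifest
  invisible(list(manifest = manifest, state = state))
}

serializable_config <- function(cfg) {
  out <- unclass(cfg)
  out <- lapply(out, function(x) if (is.list(x)) unclass(x) else x)
  out$design$tm_params <- unclass(out$design$tm_params)
  out
}
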