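#' Parse a flat key=value run-configuration file
#'
#' Unknown keys are kept verbatim; numeric-looking values are converted.
#' \code{seed} is mandatory.
#'
#' @param path config file; lines \code{key=value}, \code{#} comments
#' @return named list
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  cfg <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = "="))
    if (grepl("^-?[0-9.eE+]+$", v)) as.numeric(v) else v
  })
  names(cfg) <- trimws(vapply(kv, `[`, character(1), 1L))
  if (is.null(cfg$seed)) .fail("config must set seed")
  cfg
}

.prov_write <- function(outputs, stage, params, inputs) {
  prov <- list(stage = stage, params = params,
               inputs = as.list(tools::md5sum(inputs)),
               outputs = as.list(tools::md5sum(outputs)),
               timestamp = "fixed-for-determinism")
  jsonlite::write_json(prov, paste0(outputs[1], ".prov.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Verify provenance sidecars of a stage output
#'
#' @param output stage output file carrying a \code{.prov.json} sidecar
#' @return TRUE invisibly; warns on checksum mismatch
#' @export
check_provenance <- function(output) {
  prov <- jsonlite::read_json(paste0(output, ".prov.json"))
  ok <- TRUE
  for (f in names(prov$inputs)) {
    if (!file.exists(f) ||
        !identical(unname(tools::md5sum(f)[[1]]), prov$inputs[[f]])) {
      warning(sprintf("provenance mismatch for input %s", f))
      ok <- FALSE
    }
  }
  invisible(ok)
}

.stage_param <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run one pipeline stage
#'
#' Stages exchange data only through files under \code{outdir}; outputs are
#' written atomically (temp file + rename) with a provenance sidecar
#' recording parameters, seed and input checksums.
#'
#' @param name one of simulate, detect, annotate, quantify, tier, orf, ddct
#' @param cfg named list of parameters (see \code{\link{read_run_config}});
#'   must contain \code{seed}
#' @param outdir working directory for stage files
#' @return invisibly, the paths written
#' @export
run_stage <- function(name, cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  need <- function(f, producer) {
    if (!file.exists(p(f)))
      .fail("missing input %s (produced by stage '%s')", f, producer)
    p(f)
  }
  seed <- as.integer(cfg$seed)
  switch(
    name,
    simulate = {
      sc <- sim_config(
        seed = seed,
        n_genes = .stage_param(cfg, "n_genes", 20L),
        read_length = .stage_param(cfg, "read_length", 100L),
        depth = .stage_param(cfg, "depth", 100L),
        circular_fraction = .stage_param(cfg, "circular_fraction", 0.5),
        error_rate = .stage_param(cfg, "error_rate", 0))
      world <- make_genome_and_genes(sc)
      truth <- plant_circles(world$db, world$genome,
                             .stage_param(cfg, "n_circles", 8L),
                             sc$circular_fraction, seed = seed,
                             min_spliced_length = sc$read_length)
      reads <- simulate_reads(world$genome, world$db, truth, sc)
      write_fasta(world$genome, p("genome.fa"))
      write_gene_models(world$db, p("models.gtf"), "gtf")
      write.table(truth, p("truth_circles.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_fastq(reads, p("reads.fastq"))
      write.table(placements_from_truth(reads, world$db),
                  p("placements.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outs <- p(c("genome.fa", "models.gtf", "truth_circles.tsv",
                  "reads.fastq", "placements.tsv"))
      .prov_write(outs, "simulate", cfg, character(0))
      invisible(outs)
    },
    detect = {
      genome <- read_fasta(need("genome.fa", "simulate"))
      reads <- read_fastq(need("reads.fastq", "simulate"))
      det <- detect_backsplices(
        reads, genome,
        anchor_len = .stage_param(cfg, "anchor_len", 20L),
        min_unique_reads = .stage_param(cfg, "min_unique_reads", 2L),
        max_span = .stage_param(cfg, "max_span", 1e5))
      bed <- det$candidates
      writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", bed$chrom, bed$start,
                         bed$end, bed$circ_id, bed$junction_read_count,
                         bed$strand), p("candidates.bed"))
      write.table(det$candidates, p("candidates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(det$calls, p("call_log.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outs <- p(c("candidates.tsv", "candidates.bed", "call_log.tsv"))
      .prov_write(outs, "detect", cfg, p(c("genome.fa", "reads.fastq")))
      invisible(outs)
    },
    annotate = {
      db <- read_gene_models(need("models.gtf", "simulate"), "gtf")
      cand <- read.table(need("candidates.tsv", "detect"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
      ann <- annotate_candidates(cand, db,
                                 tol = .stage_param(cfg, "boundary_tol", 2L))
      write.table(ann, p("annotated.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(catalog_summary(ann), p("category_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- p(c("annotated.tsv", "category_summary.tsv"))
      .prov_write(outs, "annotate", cfg,
                  p(c("models.gtf", "candidates.tsv")))
      invisible(outs)
    },
    quantify = {
      ann <- read.table(need("annotated.tsv", "annotate"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
      plc <- read.table(need("placements.tsv", "simulate"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
      q <- quantify_candidates(ann, plc)
      q$junction_reads <- q$junction_read_count
      write_catalog(q, p("catalog.tsv"))
      .prov_write(p("catalog.tsv"), "quantify", cfg,
                  p(c("annotated.tsv", "placements.tsv")))
      invisible(p("catalog.tsv"))
    },
    tier = {
      cat1 <- read_catalog(need("catalog.tsv", "quantify"))
      tiers <- tier_sample(cat1,
                           top_fraction = .stage_param(cfg, "top_fraction",
                                                       0.10))
      write.table(tiers, p("tiers.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      .prov_write(p("tiers.tsv"), "tier", cfg, p("catalog.tsv"))
      invisible(p("tiers.tsv"))
    },
    orf = {
      genome <- read_fasta(need("genome.fa", "simulate"))
      db <- read_gene_models(need("models.gtf", "simulate"), "gtf")
      cat1 <- read_catalog(need("catalog.tsv", "quantify"))
      ex <- cat1[cat1$category %in% c("coding_exon", "noncoding_gene") &
                   !is.na(cat1$host_transcript), , drop = FALSE]
      peps <- list(); orfs <- list(); rl <- list()
      for (i in seq_len(nrow(ex))) {
        ring <- circular_sequence(ex[i, ], db, genome)
        o <- find_junction_orfs(ring$seq,
                                max_loops = .stage_param(cfg, "max_loops", 1L))
        if (nrow(o)) {
          o$circ_id <- ring$circ_id
          orfs[[length(orfs) + 1L]] <- o
          peps[[length(peps) + 1L]] <- junction_peptides(
            o, ring$seq, ring$circ_id,
            min_len = .stage_param(cfg, "min_pep_len", 7L),
            max_len = .stage_param(cfg, "max_pep_len", 35L),
            missed_cleavages = .stage_param(cfg, "missed_cleavages", 0L))
          rl[[ring$circ_id]] <- nchar(ring$seq)
        }
      }
      orfs <- if (length(orfs)) do.call(rbind, orfs) else
        data.frame(circ_id = character(0))
      peps <- if (length(peps)) do.call(rbind, peps) else
        data.frame(circ_id = character(0), frame = integer(0),
                   orf_start = integer(0), peptide = character(0),
                   nt_start = integer(0), nt_end = integer(0))
      write.table(orfs, p("orfs.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write_peptide_fasta(peps, rl, p("peptides.fasta"))
      outs <- p(c("orfs.tsv", "peptides.fasta"))
      .prov_write(outs, "orf", cfg,
                  p(c("genome.fa", "models.gtf", "catalog.tsv")))
      invisible(outs)
    },
    ddct = {
      samples <- data.frame(
        sample = c(paste0("case", 1:4), paste0("ctrl", 1:4)),
        group = rep(c("case", "control"), each = 4))
      targets <- data.frame(
        target = c("circX", "eif3d_spike", "GAPDH"),
        role = c("assay", "spike_in", "housekeeper"))
      effects <- data.frame(target = "circX", group = "case",
                            fold = .stage_param(cfg, "ddct_fold", 4))
      ct <- simulate_ct_table(samples, targets, effects,
                              noise_sd = .stage_param(cfg, "ddct_noise", 0.2),
                              seed = seed)
      res <- ddct_analysis(ct, control = "control")
      write.table(ct, p("ct_table.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(res$per_target, p("ddct_report.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outs <- p(c("ct_table.tsv", "ddct_report.tsv"))
      .prov_write(outs, "ddct", cfg, character(0))
      invisible(outs)
    },
    .fail("unknown stage '%s'", name))
}

#' Run the full pipeline: simulate through ddct
#'
#' Deterministic under a fixed seed: two runs produce byte-identical
#' outputs.
#'
#' @param cfg run configuration list (needs \code{seed})
#' @param outdir output directory
#' @return invisibly, \code{outdir}
#' @export
run_pipeline <- function(cfg, outdir) {
  for (st in c("simulate", "detect", "annotate", "quantify", "tier",
               "orf", "ddct"))
    run_stage(st, cfg, outdir)
  invisible(outdir)
}

#' Command-line entry point
#'
#' \code{circ_cli(c("all", "--config", "run.cfg", "--outdir", "out"))};
#' subcommands: simulate, detect, annotate, quantify, tier, orf, ddct, all.
#' \code{--seed} overrides the config seed.
#'
#' @param args character vector of CLI arguments
#' @return invisibly, outputs of the last stage run
#' @export
circ_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    .fail("usage: <subcommand> [--config FILE] [--seed N] [--outdir DIR]")
  sub <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  cfg <- if (!is.null(opt("--config"))) read_run_config(opt("--config"))
    else list()
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  if (is.null(cfg$seed)) .fail("seed required (config or --seed)")
  outdir <- opt("--outdir", "circkit_out")
  if (sub == "all") run_pipeline(cfg, outdir) else run_stage(sub, cfg, outdir)
}
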