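#' Default genome-wide state composition used by the fixture generator
#'
#' A composition shaped like a primed (serum-grown) mouse embryonic stem
#' cell methylome: most CpGs symmetrically methylated, a minority
#' unmodified, and small hemi-modified and hmC-containing fractions.
#' @return a named state-fraction vector.
#' @export
default_genome_fractions <- function() {
  state_fractions(c(MM = 0.70, CC = 0.15, MC = 0.03, CM = 0.03, HC = 0.02,
                    CH = 0.02, HM = 0.02, MH = 0.02, HH = 0.01))
}

#' Assemble a pipeline run configuration
#'
#' Collects all inputs and tunables of the decoding pipeline. Paths may be
#' \code{NULL} where a stage is optional (blacklist, regions). The
#' configuration is fully serializable (\code{\link{write_run_config}});
#' a run writes its effective configuration next to its outputs.
#'
#' @param fastq_r1,fastq_r2 paired FASTQ paths.
#' @param reference FASTA with all contigs reads may come from (sample
#'   genome plus spike-in controls).
#' @param spikein_truth TSV sidecar (\code{contig, pos0, state}) with the
#'   known states of the spike-in CpGs, or \code{NULL} to skip the
#'   confusion/correction stages.
#' @param blacklist,regions optional BED paths.
#' @param intact,cleavable,remnant_len adapter configuration (see
#'   \code{\link{hairpin_adapters}}).
#' @param max_mismatch adapter-match mismatch allowance.
#' @param k aligner seed length.
#' @param max_mismatch_rate aligner mismatch budget.
#' @param min_depth,max_errors site filters (see \code{\link{filter_sites}}).
#' @param seed integer seed recorded with the run.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(fastq_r1, fastq_r2, reference, spikein_truth = NULL,
                       blacklist = NULL, regions = NULL,
                       intact = formals(hairpin_adapters)$intact,
                       cleavable = formals(hairpin_adapters)$cleavable,
                       remnant_len = 20L, max_mismatch = 2L, k = 16L,
                       max_mismatch_rate = 0.1, min_depth = 5L,
                       max_errors = 1L, seed = 1L) {
  cfg <- list(fastq_r1 = fastq_r1, fastq_r2 = fastq_r2,
              reference = reference, spikein_truth = spikein_truth,
              blacklist = blacklist, regions = regions,
              intact = as.character(intact),
              cleavable = as.character(cleavable),
              remnant_len = as.integer(remnant_len),
              max_mismatch = as.integer(max_mismatch), k = as.integer(k),
              max_mismatch_rate = max_mismatch_rate,
              min_depth = as.integer(min_depth),
              max_errors = as.integer(max_errors), seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  for (f in c("fastq_r1", "fastq_r2", "reference")) {
    if (is.null(cfg[[f]]) || !nzchar(cfg[[f]])) {
      stop("config error: '", f, "' is required")
    }
  }
  if (is.null(cfg$intact) || is.null(cfg$cleavable) ||
      !nzchar(cfg$intact) || !nzchar(cfg$cleavable)) {
    stop("config error: adapter sequences are required")
  }
  hairpin_adapters(cfg$intact, cfg$cleavable, cfg$remnant_len)
  invisible(cfg)
}

#' Write / read a run configuration (YAML)
#'
#' @param cfg a \code{run_config}.
#' @param path YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg[vapply(cfg, is.null, logical(1))] <- list(NULL)
  do.call(run_config, cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full decoding pipeline
#'
#' Executes extract, align/call, filter, evaluate-spikeins, correct and
#' summarize in order, serializing each stage's output as TSV under
#' \code{outdir}. With \code{resume = TRUE} a stage whose output file
#' already exists is loaded instead of recomputed, making reruns
#' deterministic and cheap. Spike-in contigs (those named in the spike-in
#' truth table) are excluded from the genome-level filtering and fractions
#' and used only for the confusion matrix; per the assay's design, all
#' spike-in CpGs enter the call-rate matrix unfiltered.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param outdir output directory (created if needed).
#' @param resume reuse existing stage outputs.
#' @return invisible list with every stage's in-memory result:
#'   \code{rejects, sites, filtered, report, confusion, observed,
#'   corrected, fractions, region_summary}.
#' @export
run_pipeline <- function(cfg, outdir, resume = FALSE) {
  validate_run_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  write_run_config(cfg, file.path(outdir, "config.yaml"))
  adapters <- hairpin_adapters(cfg$intact, cfg$cleavable, cfg$remnant_len)
  logf <- function(...) message(sprintf(...))

  stage <- function(name, path, compute, reader, writer) {
    if (resume && file.exists(path)) {
      logf("[%s] reusing %s", name, path)
      return(reader(path))
    }
    res <- tryCatch(compute(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    writer(res, path)
    res
  }

  quads <- stage("extract", file.path(outdir, "quads.tsv"), function() {
    q <- extract_quads(cfg$fastq_r1, cfg$fastq_r2, adapters,
                       cfg$max_mismatch)
    jsonlite::write_json(as.list(q$rejects),
                         file.path(outdir, "rejects.json"),
                         auto_unbox = TRUE)
    logf("[extract] %d quads; rejects: %s", nrow(q$quads),
         paste(names(q$rejects), q$rejects, collapse = ", "))
    q$quads
  }, read_quads, function(res, path) write_tsv(res, path, hash))

  sites <- stage("call", file.path(outdir, "sites.tsv"), function() {
    ref <- Biostrings::readDNAStringSet(cfg$reference)
    names(ref) <- sub("\\s.*$", "", names(ref))
    idx <- ref_index(ref, cfg$k)
    al <- align_quads(quads, idx, cfg$max_mismatch_rate)
    logf("[call] aligned %d / %d quads", sum(al$aligned), nrow(al))
    al <- deduplicate(al)
    logf("[call] %d fragments after deduplication", nrow(al))
    compile_sites(call_quads(al, quads, idx))
  }, read_site_counts, function(res, path) write_site_counts(res, path))

  spike_truth <- NULL
  spike_sites <- NULL
  genome_sites <- sites
  if (!is.null(cfg$spikein_truth)) {
    spike_truth <- read_tsv(cfg$spikein_truth,
                            colClasses = c("character", "integer",
                                           "character"))
    is_spike <- sites$contig %in% unique(spike_truth$contig)
    spike_sites <- sites[is_spike, , drop = FALSE]
    genome_sites <- sites[!is_spike, , drop = FALSE]
  }

  flt <- stage("filter", file.path(outdir, "sites_filtered.tsv"), function() {
    f <- filter_sites(genome_sites, cfg$min_depth, cfg$blacklist,
                      cfg$max_errors)
    logf("[filter] removed depth=%d blacklist=%d errors=%d; retained %d",
         f$report[["depth"]], f$report[["blacklist"]],
         f$report[["errors"]], f$report[["retained"]])
    f$sites
  }, read_site_counts, function(res, path) write_site_counts(res, path))

  confusion <- NULL
  corrected <- NULL
  observed <- NULL
  if (!is.null(spike_truth)) {
    confusion <- stage("evaluate-spikeins",
                       file.path(outdir, "confusion.tsv"), function() {
      build_confusion(spike_sites, spike_truth)
    }, read_confusion, function(res, path) write_confusion(res, path))

    corrected <- stage("correct", file.path(outdir, "corrected.tsv"),
                       function() {
      observed <<- observed_fractions(flt)
      correct_fractions(observed, confusion)
    }, function(path) {
      df <- read_tsv(path)
      structure(list(estimate = setNames(df$estimate, df$state),
                     raw = setNames(df$raw, df$state),
                     residual = setNames(df$residual, df$state),
                     condition = NA_real_,
                     total = sum(df$estimate)),
                class = "corrected_fractions")
    }, function(res, path) write_corrected_fractions(res, path))
  }

  fractions <- stage("summarize", file.path(outdir, "fractions.tsv"),
                     function() site_fractions(flt),
                     function(path) {
                       structure(read_tsv(path),
                                 class = c("site_fractions", "data.frame"))
                     },
                     function(res, path) {
                       write_site_fractions(res, path)
                     })

  region_summary <- NULL
  if (!is.null(cfg$regions)) {
    region_summary <- stage("regions", file.path(outdir, "regions.tsv"),
                            function() region_means(fractions, cfg$regions),
                            read_tsv,
                            function(res, path) write_tsv(res, path, hash))
  }

  invisible(list(quads = quads, sites = sites, filtered = flt,
                 confusion = confusion, observed = observed,
                 corrected = corrected, fractions = fractions,
                 region_summary = region_summary))
}

#' Emit a small, fully self-contained test dataset
#'
#' Generates a 20 kb single-contig genome with the default state
#' composition, the nine-state spike-in panel, and simulated reads from the
#' combined reference under the default chemistry error model, then writes
#' everything (FASTA, truth TSVs, uncompressed FASTQ, config YAML) to
#' \code{dir}. Deterministic given the seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_pairs number of primary read pairs.
#' @param genome_length genome contig length (bp).
#' @param errors a \code{\link{chemistry_errors}} model.
#' @return invisible named vector of the paths written, including a ready
#'   \code{config.yaml} for \code{\link{run_pipeline}}.
#' @export
make_fixture <- function(dir, seed = 1L, n_pairs = 20000L,
                         genome_length = 20000L,
                         errors = chemistry_errors()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  adapters <- hairpin_adapters()
  genome <- generate_reference(1L, genome_length, 0.02, seed = seed)
  methylome <- assign_states(genome, default_genome_fractions(),
                             seed = seed + 1L)
  panel <- build_spikein_panel(seed = seed + 2L, adapters = adapters)
  combined <- duplex_methylome(
    c(as_ref_chars(methylome), as_ref_chars(panel)),
    rbind(methylome$states, panel$states))
  sim <- simulate_reads(combined, n_pairs, errors, adapters,
                        seed = seed + 3L)
  p <- c(reference = file.path(dir, "reference.fa"),
         genome_truth = file.path(dir, "genome_truth.tsv"),
         spikein_truth = file.path(dir, "spikein_truth.tsv"),
         r1 = file.path(dir, "reads_R1.fastq"),
         r2 = file.path(dir, "reads_R2.fastq"),
         truth = file.path(dir, "reads_truth.tsv"),
         truth_calls = file.path(dir, "reads_truth_calls.tsv"),
         config = file.path(dir, "config.yaml"))
  Biostrings::writeXStringSet(combined$reference, p[["reference"]])
  write_tsv(methylome$states, p[["genome_truth"]])
  write_tsv(panel$states, p[["spikein_truth"]])
  write_fastq(sim$r1, p[["r1"]])
  write_fastq(sim$r2, p[["r2"]])
  write_tsv(sim$truth, p[["truth"]])
  write_tsv(sim$truth_calls, p[["truth_calls"]])
  cfg <- run_config(fastq_r1 = p[["r1"]], fastq_r2 = p[["r2"]],
                    reference = p[["reference"]],
                    spikein_truth = p[["spikein_truth"]], seed = seed)
  write_run_config(cfg, p[["config"]])
  invisible(p)
}
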