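# Pipeline orchestration: a single configuration object with the canonical
# defaults, input validation, and a reproducible end-to-end run with a
# manifest.

#' Default pipeline configuration
#'
#' Every parameter defaults to the canonical analysis value: 9-nt site
#' windows, 3-covered-nt sparse filter, 3-events-per-replicate
#' reproducibility, +/-5-nt background buffer, 10-event SOB floor, 500-nt
#' UTR fallback, 55-nt stretch search space with 8-30-nt windows and
#' 0.70/11/4 keep-thresholds, 40-nt k-mer flanks with 1000x100 background
#' draws, 2001-nt and 201-nt metaprofile windows, 50-nt smoothing, and
#' -750..-650 / -150..-50 enrichment windows.
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param simulate Simulation block (a [simulation_config()] argument list)
#'   or `NULL` to run on provided inputs.
#' @param paths Named list of input paths (`genome`, `annotation`,
#'   `tracks_plus`, `tracks_minus` as vectors per replicate, `reads`);
#'   ignored when simulating.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, simulate = list(), paths = list()) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = simulate,
    paths = paths,
    barcode = list(min_qual_random = 17, min_qual_experimental = 20,
                   max_low_experimental = 1),
    peaks = list(window = 500, alpha = 0.01),
    sites = list(width = 9, min_covered = 3, min_events = 3,
                 exclude_introns = TRUE, merge_direction = "genomic"),
    annotation_filter = list(max_level = 2, max_tsl = 3, direction = "le"),
    sob = list(min_background = 10, rule = "per_replicate", buffer = 5,
               utr3_fallback = 500, past_site = 10),
    stretch = list(search_space = 55, min_size = 8, max_size = 30,
                   min_a_content = 0.70, min_weighted_a = 11, min_lca = 4,
                   exclusion = "any_fail"),
    kmers = list(flank = 40, bg_windows = 1000, bg_repeats = 100,
                 halfwindow = 50),
    polya = list(radius = 1000, min_events = 10, min_utr3 = 1000,
                 smooth = 50, signal_window = c(-150, -50),
                 body_window = c(-750, -650), stretch_radius = 100,
                 terminal_a_headline = 10)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' absent keys keep them.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = if (!is.null(user$seed)) user$seed else 1)
  for (block in names(user)) {
    if (is.list(user[[block]]) && is.list(cfg[[block]])) {
      for (k in names(user[[block]])) cfg[[block]][[k]] <- user[[block]][[k]]
    } else {
      cfg[[block]] <- user[[block]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration as YAML
#' @param config `pipeline_config`.
#' @param path Output file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Checks syntactic validity of FASTA/GTF/bedGraph/FASTQ inputs, contig-name
#' consistency across files, and strand symbols. Fatal problems and warnings
#' are distinguished.
#'
#' @param genome Path to a genome FASTA (optional).
#' @param annotation Path to a GTF (optional).
#' @param tracks Character vector of bedGraph paths (optional).
#' @param reads Path to a FASTQ (optional).
#' @return data.frame with columns `level` ("fatal"/"warning"), `check`,
#'   `message`; zero rows when everything passes. Attribute `ok` is TRUE
#'   when no fatal entry exists.
#' @export
validate_inputs <- function(genome = NULL, annotation = NULL, tracks = NULL,
                            reads = NULL) {
  probs <- list()
  note <- function(level, check, message) {
    probs[[length(probs) + 1L]] <<- data.frame(
      level = level, check = check, message = message,
      stringsAsFactors = FALSE)
  }
  contigs <- NULL
  if (!is.null(genome)) {
    if (!file.exists(genome)) {
      note("fatal", "genome", paste("missing file:", genome))
    } else {
      g <- tryCatch(read_genome_fasta(genome), error = function(e) e)
      if (inherits(g, "error")) {
        note("fatal", "genome", conditionMessage(g))
      } else {
        contigs <- names(g)
      }
    }
  }
  if (!is.null(annotation)) {
    if (!file.exists(annotation)) {
      note("fatal", "annotation", paste("missing file:", annotation))
    } else {
      a <- tryCatch(read_annotation_gtf(annotation), error = function(e) e)
      if (inherits(a, "error")) {
        note("fatal", "annotation", conditionMessage(a))
      } else if (!is.null(contigs)) {
        extra <- setdiff(unique(as.character(GenomeInfoDb::seqnames(a))),
                         contigs)
        if (length(extra)) {
          note("fatal", "annotation",
               paste("contigs absent from genome:",
                     paste(extra, collapse = ", ")))
        }
      }
    }
  }
  for (tp in tracks) {
    if (!file.exists(tp)) {
      note("fatal", "track", paste("missing file:", tp))
      next
    }
    bg <- tryCatch(utils::read.table(tp, sep = "\t"),
                   error = function(e) e)
    if (inherits(bg, "error")) {
      if (length(readLines(tp)) == 0) next  # empty strand file is valid
      note("fatal", "track", paste(tp, ":", conditionMessage(bg)))
      next
    }
    if (ncol(bg) < 4) {
      note("fatal", "track", paste(tp, ": fewer than 4 bedGraph columns"))
      next
    }
    if (!is.null(contigs)) {
      extra <- setdiff(unique(bg[[1]]), contigs)
      if (length(extra)) {
        note("fatal", "track",
             paste(tp, ": contigs absent from genome:",
                   paste(extra, collapse = ", ")))
      }
    }
    if (any(bg[[2]] < 0 | bg[[3]] <= bg[[2]])) {
      note("fatal", "track", paste(tp, ": invalid intervals"))
    }
  }
  if (!is.null(reads)) {
    if (!file.exists(reads)) {
      note("fatal", "reads", paste("missing file:", reads))
    } else {
      r <- tryCatch(read_reads_fastq(reads), error = function(e) e)
      if (inherits(r, "error")) {
        note("fatal", "reads", conditionMessage(r))
      } else if (any(nchar(r$seq) != nchar(r$qual))) {
        note("fatal", "reads", "sequence/quality length mismatch")
      }
    }
  }
  out <- if (length(probs)) do.call(rbind, probs) else
    data.frame(level = character(0), check = character(0),
               message = character(0))
  attr(out, "ok") <- !any(out$level == "fatal")
  out
}

pipeline_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop(structure(
      class = c("pipeline_stage_error", "error", "condition"),
      list(message = sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call = NULL, stage = stage, code = "stage_failure")))
  })
}

#' Run the full pipeline
#'
#' Executes simulate (or input loading) -> site calling -> SOB -> sequence
#' context -> poly(A)/metaprofiles, writing deterministic TSV/BED/bedGraph
#' outputs and a JSON manifest (config hash, seed, per-stage record counts)
#' under `outdir`. Reruns with an identical config and seed are byte-
#' identical.
#'
#' @param config `pipeline_config` (set `config$simulate` to a list of
#'   [simulation_config()] overrides to run on synthetic data, or
#'   `config$paths` to point at real inputs).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a result bundle: `sites`, `stretches`, `kmer_z`,
#'   `profiles`, `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("arichclip")),
    config_hash = digest::digest(unclass(config)),
    seed = config$seed,
    stages = list()
  )
  hash_line <- paste0("config_hash=", manifest$config_hash,
                      " seed=", config$seed)

  # --- inputs: simulate or load -------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- pipeline_stage("simulate", {
      scfg <- do.call(simulation_config,
                      c(config$simulate, list(seed = config$seed)))
      ref <- generate_reference(scfg)
      tracks <- simulate_crosslink_tracks(ref$annotation, ref$truth, scfg)
      reads <- simulate_reads(ref$truth, scfg)
      write_genome_fasta(ref$genome, file.path(outdir, "genome.fa"))
      write_annotation_gtf(ref$annotation, file.path(outdir, "annotation.gtf"))
      for (rn in names(tracks)) {
        write_track_bedgraph(
          tracks[[rn]],
          file.path(outdir, sprintf("crosslinks.%s.plus.bedgraph", rn)),
          file.path(outdir, sprintf("crosslinks.%s.minus.bedgraph", rn)))
      }
      write_reads_fastq(reads, file.path(outdir, "reads.fastq"))
      write_truth_tables(ref$truth, file.path(outdir, "truth"))
      list(genome = ref$genome, annotation = ref$annotation,
           truth = ref$truth, tracks = tracks, reads = reads)
    })
    genome <- sim$genome; annotation <- sim$annotation
    tracks <- sim$tracks; reads <- sim$reads
  } else {
    loaded <- pipeline_stage("load_inputs", {
      p <- config$paths
      rep <- validate_inputs(genome = p$genome, annotation = p$annotation,
                             tracks = c(p$tracks_plus, p$tracks_minus),
                             reads = p$reads)
      if (!attr(rep, "ok")) {
        stop("input validation failed:\n",
             paste(rep$message[rep$level == "fatal"], collapse = "\n"))
      }
      genome <- read_genome_fasta(p$genome)
      sl <- stats::setNames(Biostrings::width(genome), names(genome))
      annotation <- read_annotation_gtf(p$annotation)
      tracks <- mapply(function(pl, mi) {
        read_track_bedgraph(pl, mi, seqlengths = sl)
      }, p$tracks_plus, p$tracks_minus, SIMPLIFY = FALSE)
      names(tracks) <- sprintf("rep%d", seq_along(tracks))
      reads <- if (!is.null(p$reads)) read_reads_fastq(p$reads) else NULL
      list(genome = genome, annotation = annotation, tracks = tracks,
           reads = reads)
    })
    genome <- loaded$genome; annotation <- loaded$annotation
    tracks <- loaded$tracks; reads <- loaded$reads
  }
  manifest$stages$inputs <- list(
    n_replicates = length(tracks),
    total_crosslinks = sum(vapply(tracks, total_events, numeric(1))),
    n_reads = if (is.null(reads)) 0L else nrow(reads))

  # --- binding sites -------------------------------------------------------
  af <- config$annotation_filter
  sites <- pipeline_stage("callsites", {
    call_binding_sites(
      tracks, annotation,
      params = nb_params(config$peaks$window, config$peaks$alpha),
      width = config$sites$width, min_covered = config$sites$min_covered,
      min_events = config$sites$min_events,
      exclude_introns = config$sites$exclude_introns,
      max_level = af$max_level, max_tsl = af$max_tsl,
      direction = af$direction,
      merge_direction = config$sites$merge_direction)
  })
  manifest$stages$callsites <- as.list(attr(sites, "funnel"))

  # --- SOB -----------------------------------------------------------------
  sites <- pipeline_stage("sob", {
    compute_sob(sites, tracks, annotation,
                min_background = config$sob$min_background,
                rule = config$sob$rule, buffer = config$sob$buffer,
                utr3_fallback = config$sob$utr3_fallback,
                past_site = config$sob$past_site)
  })
  manifest$stages$sob <- list(
    n_defined = sum(sites$sob_defined),
    n_undefined = sum(!sites$sob_defined))
  write_sites_bed(sites, file.path(outdir, "sites.bed"),
                  extra_comment = hash_line)

  # --- sequence context ----------------------------------------------------
  stretch_params <- stretch_search_params(
    search_space = config$stretch$search_space,
    min_size = config$stretch$min_size, max_size = config$stretch$max_size,
    min_a_content = config$stretch$min_a_content,
    min_weighted_a = config$stretch$min_weighted_a,
    min_lca = config$stretch$min_lca, exclusion = config$stretch$exclusion)
  u3_sites <- sites[sites$region == "three_prime_utr"]
  seq_res <- pipeline_stage("arich", {
    per_site <- find_arich_stretches(u3_sites, genome, stretch_params)
    merged_st <- merge_neighboring_stretches(per_site)
    list(per_site = per_site, merged = merged_st)
  })
  manifest$stages$arich <- list(
    utr3_sites = length(u3_sites),
    sites_with_stretch = length(unique(unlist(seq_res$per_site$site_ids))),
    merged_stretches = length(seq_res$merged))
  write_stretches_bed(seq_res$merged, file.path(outdir, "stretches.bed"),
                      extra_comment = hash_line)
  lca_table <- stratify_sob_by_lca(sites, seq_res$merged)
  write_tsv(lca_table, file.path(outdir, "sob_by_lca.tsv"),
            comment = hash_line)

  kmer_z <- pipeline_stage("kmers", {
    kmer_zscores(sites, genome, annotation,
                 flank = config$kmers$flank,
                 width = config$sites$width,
                 bg_windows = config$kmers$bg_windows,
                 bg_repeats = config$kmers$bg_repeats,
                 seed = config$seed,
                 max_level = af$max_level, max_tsl = af$max_tsl,
                 direction = af$direction)
  })
  write_tsv(kmer_z, file.path(outdir, "kmer_zscores.tsv"),
            comment = hash_line)
  prof <- pipeline_stage("kmer_profile", {
    kmer_positional_profile(sites, genome,
                            halfwindow = config$kmers$halfwindow)
  })
  prof_df <- data.frame(offset = as.integer(rownames(prof)), prof,
                        check.names = FALSE)
  write_tsv(prof_df, file.path(outdir, "kmer_positional_profile.tsv"),
            comment = hash_line)
  manifest$stages$kmers <- list(
    n_kmers = length(unique(kmer_z$kmer)),
    max_abs_z = max(abs(kmer_z$z), na.rm = TRUE))

  # --- poly(A) and metaprofiles -------------------------------------------
  merged <- merge_tracks(tracks)
  polya_res <- pipeline_stage("polya", {
    out <- list()
    if (!is.null(reads)) {
      out$a_content <- read_a_content_curve(reads$seq)
      out$terminal <- terminal_a_curve(reads$seq)
      write_tsv(out$a_content$curve,
                file.path(outdir, "read_a_content_curve.tsv"),
                comment = hash_line)
      write_tsv(out$terminal, file.path(outdir, "terminal_a_curve.tsv"),
                comment = hash_line)
    }
    out
  })
  meta <- pipeline_stage("metaprofile", {
    pa <- tryCatch(
      polyA_site_metaprofile(
        merged, annotation, radius = config$polya$radius,
        min_events = config$polya$min_events,
        min_utr3 = config$polya$min_utr3, smooth = config$polya$smooth,
        signal_window = config$polya$signal_window,
        body_window = config$polya$body_window,
        max_level = af$max_level, max_tsl = af$max_tsl,
        direction = af$direction),
      error = function(e) NULL)
    st <- if (length(seq_res$merged)) {
      stretch_start_metaprofile(merged, seq_res$merged,
                                radius = config$polya$stretch_radius)
    } else NULL
    if (!is.null(pa)) {
      write_tsv(data.frame(offset = pa$offsets, signal = pa$profile,
                           smoothed = pa$smoothed),
                file.path(outdir, "polyA_metaprofile.tsv"),
                comment = sprintf("%s n_regions=%d enrichment_factor=%.6g",
                                  hash_line, pa$n_regions,
                                  pa$enrichment_factor))
    }
    if (!is.null(st)) {
      write_tsv(data.frame(offset = st$offsets, signal = st$profile),
                file.path(outdir, "stretch_metaprofile.tsv"),
                comment = sprintf("%s n_regions=%d", hash_line,
                                  st$n_regions))
      write_tsv(as.data.frame(st$matrix),
                file.path(outdir, "stretch_heatmap_matrix.tsv"),
                comment = hash_line)
    }
    list(polyA = pa, stretch = st)
  })
  manifest$stages$metaprofile <- list(
    polyA_regions = if (is.null(meta$polyA)) 0L else meta$polyA$n_regions,
    enrichment_factor = if (is.null(meta$polyA)) NA else
      meta$polyA$enrichment_factor,
    stretch_regions = if (is.null(meta$stretch)) 0L else
      meta$stretch$n_regions)
  if (!is.null(polya_res$terminal)) {
    k0 <- config$polya$terminal_a_headline
    row <- polya_res$terminal[polya_res$terminal$k == k0, ]
    manifest$stages$polya <- list(
      pct_terminal_a = if (nrow(row)) row$pct else 0)
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sites = sites, stretches = seq_res$merged,
                 kmer_z = kmer_z, profiles = meta, polya = polya_res,
                 manifest = manifest))
}
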