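# End-to-end orchestration: simulate or load a corpus, call crossovers,
# build the coldspot catalogue, filter SVs, run enrichment and annotation,
# and write a reproducible output bundle with a manifest.

#' Default pipeline configuration
#'
#' Stage parameters default to the canonical analysis constants: 10 kb CO
#' windows with 5 kb step and 1 kb merge; 1 Mb coldspot minimum; 50%
#' reciprocal overlap, 1.5x span factor and 0.3 dendrogram cut for
#' clustering; 0.001 resolution cutoff; 50 bp / 1 kb / 30 kb SV size
#' classes; 10,000 permutations; 100 kb density bandwidth; 500 kb / 50 kb
#' landscape windows.
#'
#' @param seed master seed for simulation and permutation stages.
#' @param outdir output directory.
#' @param hybrids hybrid ids to simulate/process.
#' @param n_perm permutations for enrichment stages.
#' @param sim named list of [sim_config()] overrides.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, outdir = tempfile("coldspot_run_"),
                           hybrids = c("PM", "NE", "CH", "HB", "PN"),
                           n_perm = 10000, sim = list()) {
  list(
    seed = seed,
    outdir = outdir,
    hybrids = hybrids,
    sim = sim,
    co_filter = list(min_resolution = 0.001, max_molecule_span = 500e3,
                     min_markers_per_block = 3, min_reads_per_block = 2,
                     max_wildcard_fraction = 0.1),
    co_regions = list(window = 10e3, step = 5e3, merge_gap = 1e3),
    coldspots = list(min_size = 1e6),
    clustering = list(min_reciprocal = 0.5, span_factor = 1.5,
                      cut_height = 0.3),
    sv_filter = list(min_detect_len = 50, min_analysis_len = 1000,
                     min_inv_report_len = 30e3,
                     match_reciprocal_overlap = 0.5),
    enrichment = list(n_perm = n_perm),
    landscape = list(window = 500e3, step = 50e3, bandwidth = 100e3)
  )
}

#' Run the full coldspot pipeline
#'
#' Stages: corpus (simulate with the config seed, or read from
#' `corpus_dir`) -> crossover calling -> CO regions -> coldspots ->
#' cross-hybrid clustering + conserved coldspots -> SV filtering ->
#' permutation enrichment (SVs, TE superfamilies, genes) -> genic
#' annotation. All outputs are written as deterministic TSV/BED files plus
#' a manifest carrying the config hash and seed, so identical config+seed
#' reproduce the bundle byte for byte.
#'
#' @param config configuration list from [default_config()] (or a path to
#'   a YAML file with the same structure).
#' @param corpus optional pre-built `sim_corpus`; overrides simulation.
#' @param corpus_dir optional directory written by [write_corpus()] to
#'   load instead of simulating.
#' @return invisibly, a list with the per-stage results (events,
#'   co_regions, coldspots, catalogue, conserved, svs, enrichment,
#'   annotation, paths).
#' @export
run_pipeline <- function(config = default_config(), corpus = NULL,
                         corpus_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("seed", "outdir", "hybrids", "co_filter", "co_regions",
                "coldspots", "clustering", "sv_filter", "enrichment")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config missing fields: ", paste(missing, collapse = ", "))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # --- corpus
  if (is.null(corpus)) {
    if (!is.null(corpus_dir)) {
      corpus <- read_corpus(corpus_dir)
    } else {
      cfg <- do.call(sim_config, c(config$sim,
                                   list(seed = derive_seed(config$seed, "sim"))))
      corpus <- simulate_corpus(cfg, hybrids = config$hybrids)
    }
  }
  genome <- corpus$genome
  params <- do.call(co_filter_params, config$co_filter)
  svp <- do.call(sv_filter_params, config$sv_filter)

  events <- list(); regions <- list(); coldspots <- list(); svs <- list()
  stage_log <- list()
  for (h in names(corpus$hybrids)) {
    hd <- corpus$hybrids[[h]]
    ev <- call_crossovers(hd$molecules, params, hybrid_id = h)
    reg <- build_co_regions(ev, genome,
                            window = config$co_regions$window,
                            step = config$co_regions$step,
                            merge_gap = config$co_regions$merge_gap)
    cs <- detect_coldspots(reg, genome, hd$markers,
                           min_size = config$coldspots$min_size)
    sv <- filter_parental_svs(hd$features$sv_inbred, hd$features$sv_pollen,
                              hd$features$sv_self, svp)
    events[[h]] <- ev; regions[[h]] <- reg; coldspots[[h]] <- cs
    svs[[h]] <- sv
    stage_log[[h]] <- list(n_molecule_rejections = as.list(attr(ev, "rejections")),
                           n_events = nrow(ev),
                           n_co_regions = length(reg$regions),
                           n_coldspots = length(cs),
                           n_svs_filtered = length(sv))
  }

  pooled <- suppressWarnings(do.call(c, unname(coldspots)))
  catalogue <- cluster_coldspots(pooled,
                                 min_reciprocal = config$clustering$min_reciprocal,
                                 span_factor = config$clustering$span_factor,
                                 cut_height = config$clustering$cut_height)
  conserved <- conserved_coldspots(coldspots, genome)

  # --- association statistics on the pooled CO set of the first hybrid
  # (per-hybrid tables for the rest)
  n_perm <- config$enrichment$n_perm
  feats <- corpus$features
  te_tracks <- as.list(split(feats$te, mcols(feats$te)$superfamily))
  enrich <- list()
  for (h in names(events)) {
    ev <- events[[h]]
    sv_big <- svs[[h]][mcols(svs[[h]])$analysis]
    fl <- c(list(SV = sv_big, genes = feats$genes$gr, ACR = feats$acrs),
            te_tracks)
    fl <- fl[vapply(fl, length, integer(1)) > 0]
    enrich[[h]] <- enrichment_table(ev, fl, genome, n_perm = n_perm,
                                    seed = derive_seed(config$seed,
                                                       paste0("enrich_", h)))
  }
  all_events <- do.call(rbind, unname(events))
  anno <- assign_feature(all_events, feats$genes, genome)
  genic <- count_genic_cos(all_events, feats$genes, genome)
  gene_report <- coldspot_gene_report(pooled, feats$genes)

  # --- outputs
  paths <- list()
  for (h in names(events)) {
    paths[[paste0(h, "_events")]] <-
      write_events(events[[h]],
                   tsv = file.path(outdir, paste0(h, ".events.tsv")),
                   bed = file.path(outdir, paste0(h, ".events.bed")))$tsv
    write_bed(regions[[h]]$regions,
              file.path(outdir, paste0(h, ".co_regions.bed")))
    write_svs(svs[[h]], file.path(outdir, paste0(h, ".svs_filtered.tsv")))
    fwrite(as.data.table(enrich[[h]]),
           file.path(outdir, paste0(h, ".enrichment.tsv")), sep = "\t")
  }
  write_coldspots(catalogue, tsv = file.path(outdir, "coldspot_catalogue.tsv"),
                  bed = file.path(outdir, "coldspots.bed"))
  write_bed(conserved, file.path(outdir, "conserved_coldspots.bed"))
  fwrite(as.data.table(cbind(all_events, anno)),
         file.path(outdir, "events_annotated.tsv"), sep = "\t")

  cfg_path <- file.path(outdir, "config_frozen.yaml")
  cfg_serializable <- config
  cfg_serializable$outdir <- NULL  # run location, not an analysis parameter
  cfg_serializable$sim <- lapply(config$sim, function(v)
    if (is.numeric(v) || is.character(v) || is.logical(v)) v else NULL)
  yaml::write_yaml(cfg_serializable, cfg_path)
  manifest <- list(seed = config$seed,
                   config_md5 = unname(md5sum(cfg_path)),
                   hybrids = names(events),
                   stages = stage_log,
                   summary = list(
                     n_events_total = nrow(all_events),
                     genome_bp = genome_size(genome),
                     conserved_coldspot_fraction = attr(conserved, "fraction"),
                     n_clusters = nrow(attr(catalogue, "clusters")),
                     n_unique = sum(attr(catalogue, "clusters")$class == "unique"),
                     n_shared = sum(attr(catalogue, "clusters")$class == "shared"),
                     genic = genic))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(genome = genome, events = events, co_regions = regions,
                 coldspots = coldspots, catalogue = catalogue,
                 conserved = conserved, svs = svs, enrichment = enrich,
                 annotation = anno, genic = genic,
                 gene_report = gene_report, manifest = manifest,
                 outdir = outdir))
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir corpus directory.
#' @return a `sim_corpus`-shaped list usable by [run_pipeline()].
#' @export
read_corpus <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  genome <- read_genome(file.path(dir, "genome.tsv"),
                        file.path(dir, "per.bed"))
  te <- read_bed(file.path(dir, "te.bed"))
  mcols(te)$superfamily <- mcols(te)$name
  genes <- read_gene_models(file.path(dir, "genes.gff3"), genome)
  acrs <- read_bed(file.path(dir, "acrs.bed"))
  hybrids <- list()
  for (h in manifest$hybrids) {
    svs <- read_svs(file.path(dir, paste0(h, ".svs.tsv")))
    hybrids[[h]] <- list(
      markers = read_markers(file.path(dir, paste0(h, ".markers.tsv"))),
      molecules = read_molecules(file.path(dir, paste0(h, ".molecules.tsv"))),
      truth = as.data.frame(fread(file.path(dir, paste0(h, ".truth.tsv")))),
      features = list(te = te, genes = genes, acrs = acrs,
                      sv_inbred = svs[mcols(svs)$source == "wild_inbred"],
                      sv_pollen = svs[mcols(svs)$source == "f1_pollen"],
                      sv_self = svs[mcols(svs)$source == "self"]))
  }
  structure(list(cfg = manifest$config, genome = genome,
                 features = list(te = te, genes = genes, acrs = acrs),
                 hybrids = hybrids),
            class = "sim_corpus")
}

#' Build the bundled small test corpus
#'
#' A deterministic scaled-down corpus (3 x 30 Mb chromosomes, 2 hybrids,
#' 3,000 molecules each) with planted COs, SVs and TE tracks, used by the
#' test suite; the truth tables ride along.
#'
#' @param seed master seed.
#' @param dir optional directory; when given the corpus is also written
#'   there via [write_corpus()].
#' @return a `sim_corpus`.
#' @export
make_fixture <- function(seed = 1L, dir = NULL) {
  # dense-recombination fixture: elevated co_rate so the detector sees a
  # few hundred planted events per hybrid
  cfg <- sim_config(n_molecules = 3000, co_rate = 0.12, sv_count = 60,
                    gene_count = 600, acr_count = 400, seed = seed)
  corpus <- simulate_corpus(cfg, hybrids = c("H1", "H2"))
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}
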