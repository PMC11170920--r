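#' Run the end-to-end synthetic pipeline
#'
#' Config-driven orchestration: simulate a species pair, call CpG islands
#' in both species genomes, apply the cross-species orphan filter, build
#' orthologous sites, run the label-permutation grid test and the genomic
#' shuffle test, run the expression test, and write every stage's outputs
#' plus a machine-readable `manifest.json` (inputs, parameters, seeds and
#' output checksums) into `outdir`. Stages are deterministic given the
#' config seed, so re-running the same config reproduces identical
#' checksums.
#'
#' @param config path to a YAML file, or an equivalent named list.
#'   Recognized keys are the arguments of [synthetic_spec()] plus
#'   `rounds` (permutation/shuffle rounds, default 1000).
#' @param outdir output directory (created; must not already contain a
#'   manifest).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (is.character(config) && length(config) == 1) {
    stop_if(!file.exists(config), "config file not found: %s", config)
    yaml::read_yaml(config)
  } else {
    stop_if(!is.list(config), "config must be a file path or a list")
    config
  }
  spec_args <- cfg[names(cfg) %in% names(formals(synthetic_spec))]
  spec <- do.call(synthetic_spec, spec_args)
  rounds <- cfg$rounds %||% 1000
  stop_if(dir.exists(outdir) && file.exists(file.path(outdir,
                                                      "manifest.json")),
          "outdir already holds a completed run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  seeds <- derive_seeds(spec$seed, 4)
  manifest <- list(config = cfg, spec = unclass(spec), stages = list())
  out <- function(name) file.path(outdir, name)
  add_stage <- function(name, params, files) {
    manifest$stages[[name]] <<- list(
      parameters = params,
      outputs = as.list(tools::md5sum(files)))
  }

  # 1. simulate
  pair <- make_species_pair(spec)
  write_genome_fasta(pair$A, out("genome_A.fa"))
  write_genome_fasta(pair$B, out("genome_B.fa"))
  write_bed(pair$islands[, c("chrom", "start", "end", "name")],
            out("islands_truth.bed"))
  write.table(pair$islands, out("islands_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (mn in names(pair$maps)) {
    write_coordinate_map(pair$maps[[mn]], out(paste0("map_", mn, ".tsv")))
  }
  add_stage("simulate", list(seed = spec$seed),
            c(out("genome_A.fa"), out("genome_B.fa"),
              out("islands_truth.bed"), out("islands_truth.tsv")))

  # 2. call CGIs per species
  cgi_A <- call_cgis(pair$A)
  cgi_B <- call_cgis(pair$B)
  write.table(cgi_A, out("cgi_A.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cgi_B, out("cgi_B.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  add_stage("call_cgis", unclass(cgi_params()),
            c(out("cgi_A.tsv"), out("cgi_B.tsv")))

  # 3. cross-species orphan filter (synthetic genomes carry no gene
  # annotation, so the human-intermediate mappability filter is the
  # operative exclusion)
  ocgi_A <- cross_species_filter(cgi_A, pair$maps$A_to_human)
  ocgi_B <- cross_species_filter(cgi_B, pair$maps$B_to_human)
  write.table(ocgi_A, out("ocgi_A.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ocgi_B, out("ocgi_B.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  add_stage("orphan_filter", list(), c(out("ocgi_A.tsv"),
                                       out("ocgi_B.tsv")))

  # 4. orthologous sites
  sites <- build_orthologous_sites(ocgi_A, ocgi_B,
                                   pair$maps$A_to_human,
                                   pair$maps$B_to_human,
                                   pair$maps$human_to_A,
                                   pair$maps$human_to_B,
                                   seq_A = pair$A, seq_B = pair$B)
  write.table(sites, out("sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  add_stage("orthology", list(min_match = pair$maps$A_to_human$min_match),
            out("sites.tsv"))

  # 5. peaks + grid test
  pk <- make_peaks_and_signal(pair, spec)
  labeled <- label_sites(sites, pk$peaks_A, pk$peaks_B)
  grid <- permutation_grid_test(labeled, rounds = max(100, rounds),
                                seed = seeds[1])
  jsonlite::write_json(
    list(observed = grid$observed, expected = grid$expected,
         enrichment = grid$enrichment, p = grid$p, q = grid$q,
         rounds = grid$rounds, mode = grid$mode),
    out("grid_test.json"), digits = NA, matrix = "rowmajor")
  add_stage("grid_test", list(rounds = grid$rounds, seed = seeds[1]),
            out("grid_test.json"))

  # 6. shuffle test (species A)
  chrom_sizes <- nchar(pair$A)
  sh <- shuffle_test(ocgi_A, pk$peaks_A, chrom_sizes,
                     excluded = pair$masked, rounds = min(rounds, 1000),
                     seed = seeds[2])
  jsonlite::write_json(sh[c("observed", "expected", "p_value")],
                       out("shuffle_test.json"), digits = NA,
                       auto_unbox = TRUE)
  add_stage("shuffle_test", list(rounds = min(rounds, 1000),
                                 seed = seeds[2]),
            out("shuffle_test.json"))

  # 7. expression test against the planted gene sets
  genes <- make_expression(spec)
  tpm_A <- compute_tpm(genes$counts_A, genes$exon_length_bp, genes$id)
  tpm_B <- compute_tpm(genes$counts_B, genes$exon_length_bp, genes$id)
  assign <- setNames(genes$set_truth, genes$id)
  expr <- expression_ratio_test(assign, tpm_A, tpm_B,
                                rounds = min(rounds, 2000),
                                seed = seeds[3])
  write.table(as.data.frame(expr), out("expression_test.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  add_stage("expression_test", list(rounds = min(rounds, 2000),
                                    seed = seeds[3]),
            out("expression_test.tsv"))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
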