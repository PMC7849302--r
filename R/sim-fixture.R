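# Fixture bundle assembly and plain-text serialization.

#' Simulate a complete fixture bundle
#'
#' Runs [simulate_truth()], [simulate_fraction_counts()] and
#' [simulate_aux_data()] and collects everything the pipeline consumes.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle`: `config`, `truth`, `counts`,
#'   `samples`, `library_scales`, `annotation`, `cyt_nuc`, `ribo`,
#'   `ago2_peaks`, `orf_scores`, `mirnas`.
#' @export
simulate_bundle <- function(config) {
  truth <- simulate_truth(config)
  fc <- simulate_fraction_counts(truth, config)
  aux <- simulate_aux_data(truth, config)
  structure(c(list(config = config, truth = truth, counts = fc$counts,
                   samples = fc$samples, library_scales = fc$library_scales),
              aux),
            class = "sim_bundle")
}

.write_tsv <- function(df, path) {
  # full-precision numeric formatting so the fixture round-trips exactly
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a fixture bundle to plain-text files
#'
#' Serializes the bundle as TSV/BED/FASTA/YAML plus a JSON manifest
#' recording file paths and the generator seed. Files round-trip through
#' [read_fixture()] exactly.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if missing).
#' @return (invisibly) the manifest as a list.
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", dir, call. = FALSE)

  paths <- list(
    counts = "counts.tsv", samples = "samples.tsv",
    library_scales = "library_scales.tsv", truth = "truth_genes.tsv",
    annotation = "annotation.tsv", cyt_nuc = "cyt_nuc_expression.tsv",
    ribo = "ribo_counts.tsv", ago2_peaks = "ago2_peaks.bed",
    orf_scores = "orf_scores.bed", mirnas = "mirnas.fa",
    config = "config.yaml", manifest = "manifest.json")
  fp <- function(nm) file.path(dir, paths[[nm]])

  cdf <- data.frame(gene = rownames(bundle$counts), bundle$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(cdf, fp("counts"))
  .write_tsv(bundle$samples, fp("samples"))
  .write_tsv(bundle$library_scales, fp("library_scales"))
  .write_tsv(as.data.frame(bundle$truth), fp("truth"))
  .write_tsv(bundle$annotation, fp("annotation"))
  .write_tsv(bundle$cyt_nuc, fp("cyt_nuc"))
  .write_tsv(bundle$ribo, fp("ribo"))
  rtracklayer::export(bundle$ago2_peaks, fp("ago2_peaks"), format = "BED")
  rtracklayer::export(bundle$orf_scores, fp("orf_scores"), format = "BED")
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(bundle$mirnas),
                              fp("mirnas"))
  cfg <- unclass(bundle$config)
  yaml::write_yaml(cfg, fp("config"))

  manifest <- list(seed = bundle$config$seed,
                   files = paths[names(paths) != "manifest"])
  jsonlite::write_json(manifest, fp("manifest"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle back from disk
#'
#' @param dir directory written by [write_fixture()].
#' @return list with the same components as [simulate_bundle()].
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fp <- function(nm) file.path(dir, manifest$files[[nm]])

  cdf <- .read_tsv(fp("counts"))
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$gene
  storage.mode(counts) <- "integer"

  cfg <- yaml::read_yaml(fp("config"))
  cfg$seed <- as.integer(cfg$seed)
  cfg <- structure(cfg, class = "sim_config")

  mir <- Biostrings::readRNAStringSet(fp("mirnas"))

  structure(list(
    config = cfg,
    truth = structure(.read_tsv(fp("truth")),
                      class = c("truth_table", "data.frame")),
    counts = counts,
    samples = .read_tsv(fp("samples")),
    library_scales = .read_tsv(fp("library_scales")),
    annotation = .read_tsv(fp("annotation")),
    cyt_nuc = .read_tsv(fp("cyt_nuc")),
    ribo = .read_tsv(fp("ribo")),
    ago2_peaks = rtracklayer::import(fp("ago2_peaks"), format = "BED"),
    orf_scores = rtracklayer::import(fp("orf_scores"), format = "BED"),
    mirnas = stats::setNames(as.character(mir), names(mir)),
    manifest = manifest
  ), class = "sim_bundle")
}
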