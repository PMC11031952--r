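#' Run the full motif-discovery pipeline
#'
#' End-to-end workflow on one dataset: load labeled sequences (or generate a
#' synthetic planted-motif benchmark), k-mer split, stratified 80/10/10
#' split, heterogeneous-graph construction over the training records with
#' the full-dataset vocabulary, attention-network training with
#' best-validation-F1 model selection, test-set metrics, attention
#' collection and denoising over all records, seed finding, coexisting-
#' probability chaining, overlap merging and PPM construction. All documented
#' artifacts are written under \code{out_dir}:
#' \code{sequences.fasta} (when simulating), \code{ground_truth.tsv},
#' \code{split.tsv}, \code{checkpoint.json}, \code{training_log.json},
#' \code{metrics.tsv}, \code{motifs.meme}, \code{tfbs.bed},
#' \code{provenance.json}.
#'
#' @param out_dir Output directory (created).
#' @param fasta Optional labeled FASTA (headers \code{id|label}); when
#'   \code{NULL} a synthetic dataset is generated.
#' @param motif_spec A [planted_motif_spec()] for simulation (default: the
#'   bundled AP-1-like 8-mer at occurrence rate 1).
#' @param n_pos Synthetic positives (default 500).
#' @param seq_len Synthetic sequence length (default 101).
#' @param lenk K-mer length (default 5).
#' @param d_k Embedding dimension (default 100).
#' @param epochs Training epochs (default 300).
#' @param learning_rate,decay,dropout Training hyperparameters (defaults
#'   0.02, 0.001, 0.3).
#' @param theta_co Seed-chaining threshold (default 0.5).
#' @param min_support Minimum instances per motif width (default 5).
#' @param seed Master RNG seed for simulation, splitting and training.
#' @return List with \code{metrics} (a [compute_metrics()] report),
#'   \code{motifs}, \code{instances}, \code{model}, \code{split},
#'   \code{records} and \code{files} (paths written), invisibly printable.
#' @export
run_pipeline <- function(out_dir, fasta = NULL,
                         motif_spec = planted_motif_spec(default_planted_ppm()),
                         n_pos = 500L, seq_len = 101L, lenk = 5L,
                         d_k = 100L, epochs = 300L, learning_rate = 0.02,
                         decay = 0.001, dropout = 0.3, theta_co = 0.5,
                         min_support = 5L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  if (is.null(fasta)) {
    sim <- generate_synthetic(motif_spec, n_pos = n_pos, seq_len = seq_len,
                              lenk = lenk, seed = seed)
    records <- sim$records
    files$fasta <- file.path(out_dir, "sequences.fasta")
    write_seq_fasta(records, files$fasta)
    files$ground_truth <- file.path(out_dir, "ground_truth.tsv")
    write_ground_truth(sim$ground_truth, files$ground_truth)
  } else {
    records <- split_kmers(read_seq_fasta(fasta), lenk = lenk)
    files$fasta <- fasta
  }

  split <- make_split(records, seed = seed)
  files$split <- file.path(out_dir, "split.tsv")
  write_split_tsv(split, files$split)

  vocab <- build_vocab(records, lenk)
  graph <- build_het_graph(split$train, lenk = lenk, vocab = vocab)
  config <- gat_config(epochs = epochs, learning_rate = learning_rate,
                       decay = decay, dropout = dropout, lenk = lenk,
                       d_k = d_k, seed = seed)
  model <- train_gat(graph, validation = split$validation, config = config)
  files$checkpoint <- file.path(out_dir, "checkpoint.json")
  save_gat_model(model, files$checkpoint)
  files$training_log <- file.path(out_dir, "training_log.json")
  jsonlite::write_json(model$trace, files$training_log, digits = NA,
                       na = "null")

  probs <- predict(model, split$test)
  metrics <- compute_metrics(record_labels(split$test), probs)
  files$metrics <- file.path(out_dir, "metrics.tsv")
  write_metrics_tsv(metrics, files$metrics)

  att <- collect_attention(model, records)
  seeds <- find_kmer_seeds(att, records)
  stats <- coexist_stats(vocab, split$train)
  candidates <- merge_seeds(seeds, stats, records, theta_co = theta_co,
                            lenk = lenk)
  instances <- merge_overlaps(candidates, records)
  motifs <- build_motifs(instances, min_support = min_support)
  if (length(motifs) > 0L) {
    files$meme <- file.path(out_dir, "motifs.meme")
    write_meme(motifs, files$meme,
               background_freqs = positive_base_freqs(records))
    files$bed <- file.path(out_dir, "tfbs.bed")
    write_tfbs_bed(instances, files$bed)
  }

  files$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(seed = seed, lenk = lenk, d_k = d_k, epochs = epochs,
         learning_rate = learning_rate, decay = decay, dropout = dropout,
         theta_co = theta_co, min_support = min_support,
         n_records = length(records), n_seeds = nrow(seeds),
         n_instances = nrow(instances), n_motifs = length(motifs),
         r_version = as.character(getRversion()),
         input_sha256 = unname(tools::md5sum(files$fasta)),
         package_version = as.character(utils::packageVersion("gatmotif"))),
    files$provenance, auto_unbox = TRUE, pretty = TRUE)

  structure(list(metrics = metrics, motifs = motifs, instances = instances,
                 seeds = seeds, model = model, split = split,
                 records = records, files = files),
            class = "gatmotif_run")
}

#' @export
print.gatmotif_run <- function(x, ...) {
  cat("<gatmotif_run>\n")
  print(x$metrics)
  cat(sprintf("  %d seed(s) -> %d instance(s) -> %d motif(s)\n",
              nrow(x$seeds), nrow(x$instances), length(x$motifs)))
  invisible(x)
}

# Empirical A/C/G/T composition of the positive sequences (MEME background).
positive_base_freqs <- function(records) {
  pos <- records[record_labels(records) == 1L]
  chars <- unlist(strsplit(record_sequences(pos), ""), use.names = FALSE)
  counts <- tabulate(factor(chars, levels = DNA_BASES), nbins = 4L)
  counts / sum(counts)
}

write_split_tsv <- function(split, path) {
  df <- rbind(
    data.frame(id = record_ids(split$train), part = "train"),
    data.frame(id = record_ids(split$validation), part = "validation"),
    data.frame(id = record_ids(split$test), part = "test"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_split_tsv <- function(records, path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  by_id <- stats::setNames(records, record_ids(records))
  list(train = unname(by_id[df$id[df$part == "train"]]),
       validation = unname(by_id[df$id[df$part == "validation"]]),
       test = unname(by_id[df$id[df$part == "test"]]))
}
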