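## FASTQ input, run configuration and the end-to-end pipeline driver.

## gzip detection by magic bytes, not extension
open_maybe_gz <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) &&
      magic[2] == as.raw(0x8b)) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
}

#' Read a FASTQ file (Phred+33)
#'
#' Plain or gzip-compressed (detected by magic bytes). Malformed records
#' (missing `@`/`+` markers, sequence/quality length mismatch, truncated
#' final record) raise a format error naming the offending line.
#'
#' @param path FASTQ path.
#' @return a `read_set` data frame: `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) {
    out <- data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    return(out)
  }
  if (length(lines) %% 4L != 0L) {
    bs_stop(sprintf("truncated FASTQ record at line %d",
                    4L * (length(lines) %/% 4L) + 1L),
            "bs_format_error")
  }
  m <- matrix(lines, nrow = 4L)
  bad_at <- !startsWith(m[1, ], "@")
  if (any(bad_at)) {
    bs_stop(sprintf("missing '@' header at line %d",
                    4L * (which(bad_at)[1] - 1L) + 1L),
            "bs_format_error")
  }
  bad_plus <- !startsWith(m[3, ], "+")
  if (any(bad_plus)) {
    bs_stop(sprintf("missing '+' separator at line %d",
                    4L * (which(bad_plus)[1] - 1L) + 3L),
            "bs_format_error")
  }
  mism <- nchar(m[2, ]) != nchar(m[4, ])
  if (any(mism)) {
    i <- which(mism)[1]
    bs_stop(sprintf("sequence/quality length mismatch in record %s (line %d)",
                    sub("^@", "", sub("\\s.*$", "", m[1, i])),
                    4L * (i - 1L) + 2L),
            "bs_format_error")
  }
  out <- data.frame(
    read_id = sub("^@", "", sub("\\s.*$", "", m[1, ])),
    sequence = m[2, ],
    quality = m[4, ],
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_set", "data.frame")
  out
}

## tiny FNV-1a hash so outputs can carry a config fingerprint without
## external dependencies
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' @param fastq input FASTQ path.
#' @param catalog a [block_catalog()] or a catalog TSV path.
#' @param adapter5,adapter3 adapter sequences (required when `catalog` is a
#'   TSV path).
#' @param out_dir output directory (created if missing); `NULL` suppresses
#'   file output.
#' @param seed integer seed recorded in every output header.
#' @param window,q_threshold,anchor_len decoding parameters.
#' @param yaml path to a YAML file supplying any of the above (explicit
#'   arguments win over file values).
#' @return a `run_config` list.
#' @export
run_config <- function(fastq = NULL, catalog = NULL, adapter5 = NULL,
                       adapter3 = NULL, out_dir = NULL, seed = NULL,
                       window = NULL, q_threshold = NULL, anchor_len = NULL,
                       yaml = NULL) {
  cfg <- list(fastq = fastq, catalog = catalog, adapter5 = adapter5,
              adapter3 = adapter3, out_dir = out_dir, seed = seed,
              window = window, q_threshold = q_threshold,
              anchor_len = anchor_len)
  if (!is.null(yaml)) {
    fromfile <- yaml::read_yaml(yaml)
    ## explicit arguments win: only fields the caller left NULL are filled
    for (nm in intersect(names(fromfile), names(cfg))) {
      if (is.null(cfg[[nm]])) cfg[[nm]] <- fromfile[[nm]]
    }
  }
  defaults <- list(seed = 1L, window = 50, q_threshold = 15, anchor_len = 8)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$fastq) || is.null(cfg$catalog)) {
    bs_stop("run_config requires 'fastq' and 'catalog'", "bs_config_error")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full decoding pipeline
#'
#' Trims, N-filters, extracts, decodes and classifies the reads, then
#' aggregates every library statistic and (optionally) writes the TSV
#' outputs and a YAML report. The accounting is conservative at every
#' stage (input = kept + removed) and the report records the seed and a
#' config fingerprint; reruns with the same config are identical.
#'
#' @param config a [run_config()].
#' @return list with `decoded`, `report`, `cooccurrence`, `representation`,
#'   `nonredundant`, `aa_freq`, `accuracy`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  catalog <- config$catalog
  if (is.character(catalog)) {
    catalog <- read_catalog(catalog, adapter5 = config$adapter5,
                            adapter3 = config$adapter3)
  }
  set.seed(config$seed)
  reads <- read_fastq(config$fastq)
  decoded <- decode_reads(reads, catalog, window = config$window,
                          q_threshold = config$q_threshold,
                          anchor_len = config$anchor_len)
  acct <- attr(decoded, "accounting")
  cats <- table(decoded$category)
  co <- cooccurrence(decoded, catalog)
  rep_tab <- representation_counts(decoded, catalog)
  nr <- nonredundant_counts(decoded)
  aa <- rbind(aa_frequencies(catalog),
              if (any(!is.na(decoded$peptide))) aa_frequencies(decoded))
  acc <- per_length_accuracy(decoded)

  ## fingerprint the analysis parameters; the output location is not part
  ## of the analysis identity
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  report <- list(
    seed = config$seed,
    config_hash = hash,
    raw_reads = acct$n_in[1],
    discarded_n_filter = acct$n_removed[acct$stage == "n_filter"],
    remaining_after_n_filter = acct$n_kept[acct$stage == "n_filter"],
    extracted = nrow(decoded),
    not_extractable = acct$n_removed[acct$stage == "anchor_extraction"],
    category_counts = as.list(cats),
    category_percent = as.list(round(100 * cats / max(1, sum(cats)), 4))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf("seed=%s config=%s", config$seed, hash)
    wt <- function(df, name, row_names = FALSE, col_names = TRUE) {
      p <- file.path(config$out_dir, name)
      con <- file(p, "w")
      writeLines(paste0("# ", hdr), con)
      write.table(df, con, sep = "\t", quote = FALSE,
                  row.names = row_names, col.names = col_names)
      close(con)
    }
    wt(decoded, "per_read.tsv")
    wt(co, "cooccurrence.tsv", row_names = TRUE, col_names = NA)
    wt(rep_tab, "representation.tsv")
    wt(nr, "nonredundant.tsv")
    wt(aa, "aa_freq.tsv")
    wt(acc, "accuracy.tsv")
    yaml::write_yaml(report, file.path(config$out_dir, "report.yaml"))
  }
  list(decoded = decoded, report = report, cooccurrence = co,
       representation = rep_tab, nonredundant = nr, aa_freq = aa,
       accuracy = acc, accounting = acct)
}

#' Stage accounting ledger
#'
#' Conservation check used throughout the pipeline: at every stage the
#' input count must equal kept plus removed. Returns the remaining count.
#'
#' @param n_in reads entering the stage.
#' @param n_removed reads removed by the stage.
#' @return `n_in - n_removed`, after asserting non-negativity.
#' @examples
#' stage_remaining(1396867, 64019) # 1332848
#' @export
stage_remaining <- function(n_in, n_removed) {
  if (n_removed < 0 || n_removed > n_in) {
    bs_stop("stage accounting violated: removed outside [0, n_in]",
            "bs_config_error")
  }
  n_in - n_removed
}
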