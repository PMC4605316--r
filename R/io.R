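# Readers and writers for the plain-text formats the pipeline touches.
# Conventions, fixed across the package:
#   * internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
#     BED (0-based half-open) are converted on ingest and restored on write;
#   * sequences are uppercased and U is normalized to T on ingest; writers can
#     restore the RNA alphabet via `alphabet = "RNA"`;
#   * the NA token in all TSVs is "NA";
#   * repeat consensus placement travels in GFF3 attributes under the
#     documented keys `family`, `consensus_offset`, `consensus_length`.

#' Read sequences from FASTA or FASTQ
#'
#' @param path File path.
#' @param format `"fasta"` or `"fastq"`; guessed from the extension when
#'   `NULL`.
#' @return A tibble with columns `id` and `sequence` (uppercase DNA, U
#'   normalized to T); the original alphabet ("DNA" or "RNA") is recorded in
#'   the `alphabet` attribute. An empty file yields an empty tibble.
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  format <- match.arg(tolower(format), c("fasta", "fastq"))
  if (file.size(path) == 0) {
    out <- tibble::tibble(id = character(), sequence = character())
    attr(out, "alphabet") <- "DNA"
    return(out)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", format, " record in ", path, ": ",
                             conditionMessage(e))
  )
  raw <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  alphabet <- if (any(grepl("[Uu]", raw))) "RNA" else "DNA"
  seqs <- normalize_dna(raw)
  if (any(grepl("[^ACGTN]", seqs))) {
    bad <- which(grepl("[^ACGTN]", seqs))[1]
    stop("malformed record '", ids[bad], "' in ", path,
         ": non-nucleotide characters")
  }
  out <- tibble::tibble(id = ids, sequence = unname(seqs))
  attr(out, "alphabet") <- alphabet
  out
}

#' Write sequences to FASTA
#'
#' @param x Tibble with columns `id`, `sequence`, or a named character vector.
#' @param path Output path.
#' @param alphabet `"DNA"` (default) writes as-is; `"RNA"` restores U for T.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (is.character(x)) x <- tibble::tibble(id = names(x), sequence = unname(x))
  seqs <- x$sequence
  if (alphabet == "RNA") seqs <- chartr("T", "U", seqs)
  writeLines(paste0(">", x$id, "\n", seqs), path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  x <- read_sequences(path, format = "fasta")
  setNames(x$sequence, x$id)
}

# ---- GFF3 / BED ------------------------------------------------------------

gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
  vapply(m, function(v) if (length(v) == 2) v[2] else NA_character_, character(1))
}

#' Read gene/repeat models from GFF3 and interval sets from BED
#'
#' GFF3 is 1-based inclusive and converted to the internal 0-based half-open
#' convention on ingest. Gene rows (`type = gene`) carry `ID` and `biotype`
#' attributes; sub-features (`exon`, `intron`, `five_prime_UTR`,
#' `three_prime_UTR`, `CDS`) carry `Parent`. Repeat rows
#' (`type = repeat_region`) carry `family`, `consensus_offset` and
#' `consensus_length` attributes.
#'
#' @param gff_path GFF3 path.
#' @param bed_paths Optional named character vector of BED6 paths (CLIP peaks,
#'   TAR regions, ...).
#' @return A list with `models` (list of `genes` and `features` tibbles),
#'   `repeats` (tibble) and `bed` (named list of interval tibbles).
#' @export
read_models <- function(gff_path, bed_paths = NULL) {
  lines <- readLines(gff_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    fields <- matrix(character(), ncol = 9)
  } else {
    fields <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    if (ncol(fields) != 9) stop("malformed GFF3: expected 9 columns in ", gff_path)
  }
  tb <- tibble::tibble(
    chrom = fields[, 1], type = fields[, 3],
    start = as.integer(fields[, 4]) - 1L, end = as.integer(fields[, 5]),
    strand = fields[, 7], attrs = fields[, 9]
  )
  bad <- which(!(tb$start >= 0 & tb$start < tb$end))
  if (length(bad) > 0) {
    stop("coordinate inversion after GFF conversion at line: ", lines[bad[1]])
  }
  is_rep <- tb$type == "repeat_region"
  reps <- tb[is_rep, ]
  repeats <- tibble::tibble(
    chrom = reps$chrom, start = reps$start, end = reps$end,
    strand = reps$strand,
    family = gff_attr(reps$attrs, "family"),
    consensus_offset = as.integer(gff_attr(reps$attrs, "consensus_offset")),
    consensus_length = as.integer(gff_attr(reps$attrs, "consensus_length"))
  )
  gn <- tb[tb$type == "gene", ]
  genes <- tibble::tibble(
    gene_id = gff_attr(gn$attrs, "ID"), chrom = gn$chrom, start = gn$start,
    end = gn$end, strand = gn$strand, biotype = gff_attr(gn$attrs, "biotype")
  )
  ft <- tb[!is_rep & tb$type != "gene", ]
  feature_map <- c(exon = "exon", intron = "intron", five_prime_UTR = "five_utr",
                   three_prime_UTR = "three_utr", CDS = "cds")
  features <- tibble::tibble(
    gene_id = gff_attr(ft$attrs, "Parent"),
    feature = unname(feature_map[ft$type]),
    chrom = ft$chrom, start = ft$start, end = ft$end, strand = ft$strand
  )
  bed <- lapply(bed_paths %||% character(), read_bed)
  list(models = list(genes = genes, features = features),
       repeats = repeats, bed = bed)
}

#' Write gene and repeat models to GFF3
#'
#' Inverse of [read_models()]: internal 0-based half-open coordinates are
#' written as 1-based inclusive GFF3.
#'
#' @param models List of `genes` and `features` tibbles (may be `NULL`).
#' @param repeats Repeat tibble (may be `NULL`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, repeats, path) {
  lines <- "##gff-version 3"
  if (!is.null(models) && nrow(models$genes) > 0) {
    g <- models$genes
    lines <- c(lines, sprintf("%s\trsrnakit\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$biotype))
    type_map <- c(exon = "exon", intron = "intron", five_utr = "five_prime_UTR",
                  three_utr = "three_prime_UTR", cds = "CDS")
    f <- models$features
    lines <- c(lines, sprintf("%s\trsrnakit\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                              f$chrom, type_map[f$feature], f$start + 1L, f$end,
                              f$strand, f$gene_id))
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    r <- repeats
    lines <- c(lines, sprintf(
      "%s\trsrnakit\trepeat_region\t%d\t%d\t.\t%s\t.\tfamily=%s;consensus_offset=%d;consensus_length=%d",
      r$chrom, r$start + 1L, r$end, r$strand, r$family,
      r$consensus_offset, r$consensus_length))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of intervals
#'
#' BED is already 0-based half-open, matching the internal convention.
#'
#' @param path BED path.
#' @return Interval tibble with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  cols <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(cols) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = double(), strand = character()))
  }
  out <- tibble::tibble(
    chrom = as.character(cols[[1]]), start = as.integer(cols[[2]]),
    end = as.integer(cols[[3]]),
    name = if (ncol(cols) >= 4) as.character(cols[[4]]) else ".",
    score = if (ncol(cols) >= 5) as.numeric(cols[[5]]) else 0,
    strand = if (ncol(cols) >= 6) as.character(cols[[6]]) else "+"
  )
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad) > 0) stop("BED coordinate inversion at row ", bad[1], " of ", path)
  out
}

#' Write intervals to BED6
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     x$chrom, x$start, x$end,
                     x$name %||% ".",
                     format(x$score %||% 0, trim = TRUE),
                     x$strand %||% "+"), path)
  invisible(path)
}

# ---- TSV tables ------------------------------------------------------------

#' Read a TSV table with schema validation
#'
#' @param path TSV path with a header row; the NA token is "NA".
#' @param required Character vector of column names that must be present.
#' @return A tibble.
#' @export
read_table_tsv <- function(path, required = NULL) {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  x
}

#' Write a tibble to TSV
#'
#' Reals are serialized with 15 significant digits so numeric tables
#' round-trip losslessly at documented precision; the NA token is "NA".
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  fmt <- vapply(x, function(col) {
    if (is.double(col)) {
      ifelse(is.na(col), "NA", sprintf("%.15g", col))
    } else {
      ifelse(is.na(col), "NA", as.character(col))
    }
  }, FUN.VALUE = character(nrow(x)))
  if (nrow(x) == 1) fmt <- matrix(fmt, nrow = 1)
  lines <- c(paste(names(x), collapse = "\t"),
             apply(fmt, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
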