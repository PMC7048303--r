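# Readers and writers for every external format the pipeline touches.
# All internal coordinates are 0-based half-open; depth input is accepted
# 1-based (samtools-depth dialect); BED output is 0-based half-open.
# All writers emit UTF-8 with LF line endings.

#' Read CDS sequences from a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, ambiguity codes other
#' than `N` are mapped to `N`, and CDS whose length is not a multiple of 3
#' are trimmed at the 3' end to the nearest codon with a warning.  Input
#' order is preserved.
#'
#' @param path FASTA file
#' @return data.frame with columns `gene_id`, `cds`
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty)) {
    first <- nonempty[1]
    if (!startsWith(lines[first], ">")) {
      stop(sprintf("%s: line %d: expected a FASTA header ('>')", path, first),
           call. = FALSE)
    }
    hdr <- which(startsWith(lines, ">"))
    bad <- hdr[lines[hdr] == ">"]
    if (length(bad)) {
      stop(sprintf("%s: line %d: empty FASTA header", path, bad[1]), call. = FALSE)
    }
    # header immediately followed by another header / EOF = empty sequence
    nxt <- c(hdr[-1], length(lines) + 1L)
    seq_len_per <- vapply(seq_along(hdr), function(i) {
      block <- lines[setdiff(seq(hdr[i] + 1L, length.out = nxt[i] - hdr[i] - 1L),
                             integer(0))]
      sum(nchar(trimws(block)))
    }, integer(1))
    if (any(seq_len_per == 0L)) {
      stop(sprintf("%s: line %d: record with empty sequence",
                   path, hdr[which(seq_len_per == 0L)[1]]), call. = FALSE)
    }
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs <- gsub("[^ACGT]", "N", seqs)
  ids <- sub("\\s.*$", "", names(set))
  off <- nchar(seqs) %% 3L
  if (any(off != 0L)) {
    warning(sprintf("%d CDS trimmed at the 3' end to a codon multiple (%s)",
                    sum(off != 0L),
                    paste(utils::head(ids[off != 0L], 3), collapse = ", ")),
            call. = FALSE)
    seqs <- substr(seqs, 1L, nchar(seqs) - off)
  }
  data.frame(gene_id = ids, cds = unname(seqs), stringsAsFactors = FALSE)
}

#' Write CDS sequences to FASTA
#'
#' @param genes data.frame with `gene_id`, `cds`
#' @param path output file
#' @param width line wrap width
#' @export
write_cds_fasta <- function(genes, path, width = 70) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(genes))) {
    seq <- genes$cds[i]
    chunks <- substring(seq, seq(1, nchar(seq), width),
                        pmin(seq(width, nchar(seq) + width - 1, width), nchar(seq)))
    writeLines(c(paste0(">", genes$gene_id[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Read a similarity hit table (BLAST outfmt-6 dialect)
#'
#' Reads a 12-column tab-separated hit table, removes self-hits, drops hits
#' above `max_evalue`, and collapses reciprocal duplicates (a,b)/(b,a) to a
#' single hit keeping the best (largest) bitscore.
#'
#' @param path tab-separated file, 12 columns (query, subject, identity,
#'   length, mismatches, gaps, qstart, qend, sstart, send, evalue, bitscore)
#' @param max_evalue retain hits with `evalue <= max_evalue` (default 1e-20)
#' @return data.frame with `query_id`, `subject_id`, `evalue`, `bitscore`,
#'   ids ordered so `query_id < subject_id`
#' @export
read_hits <- function(path, max_evalue = 1e-20) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (max_evalue < 0) stop("max_evalue must be non-negative", call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#",
                           colClasses = c("character", "character",
                                          rep("NULL", 8), "character", "character"))
  if (nrow(tab) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bitscore = numeric()))
  }
  names(tab) <- c("query_id", "subject_id", "evalue", "bitscore")
  ev <- suppressWarnings(as.numeric(tab$evalue))
  if (anyNA(ev)) {
    stop(sprintf("%s: non-numeric evalue '%s'", path, tab$evalue[which(is.na(ev))[1]]),
         call. = FALSE)
  }
  bs <- suppressWarnings(as.numeric(tab$bitscore))
  if (anyNA(bs)) {
    stop(sprintf("%s: non-numeric bitscore '%s'", path, tab$bitscore[which(is.na(bs))[1]]),
         call. = FALSE)
  }
  tab$evalue <- ev
  tab$bitscore <- bs
  tab <- tab[tab$query_id != tab$subject_id & tab$evalue <= max_evalue, ,
             drop = FALSE]
  if (nrow(tab) == 0L) return(tab[, c("query_id", "subject_id", "evalue", "bitscore")])
  a <- pmin(tab$query_id, tab$subject_id)
  b <- pmax(tab$query_id, tab$subject_id)
  tab$query_id <- a
  tab$subject_id <- b
  ord <- order(a, b, -tab$bitscore, tab$evalue)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(paste(tab$query_id, tab$subject_id, sep = "\r")), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a hit table (outfmt-6 dialect)
#'
#' Emits the 12-column tab-separated dialect [read_hits()] accepts, with
#' placeholder values for the alignment-detail columns.
#'
#' @param hits data.frame with `query_id`, `subject_id`, `evalue`, `bitscore`
#' @param path output file
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  tab <- data.frame(hits$query_id, hits$subject_id, rep(100, n), rep(0L, n),
                    rep(0L, n), rep(0L, n), rep(1L, n), rep(0L, n), rep(1L, n),
                    rep(0L, n),
                    formatC(hits$evalue, format = "e", digits = 2),
                    hits$bitscore)
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read male/female pooled depth tracks
#'
#' Accepts a 4-column TSV (contig, 1-based position, male depth, female
#' depth; samtools-depth dialect).  Positions need not be contiguous:
#' missing positions up to each contig's maximum reported position are
#' filled with depth 0.  Internally positions are 0-based.
#'
#' @param path TSV file
#' @return named list of `depth_track` objects, one per contig, each a list
#'   with `contig`, `male_depth`, `female_depth` (position `i` of the vector
#'   is 0-based position `i - 1`)
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("contig", "pos", "male", "female"),
                           colClasses = c("character", "integer", "numeric",
                                          "numeric"))
  if (any(tab$male < 0 | tab$female < 0)) {
    stop(path, ": negative depth value", call. = FALSE)
  }
  if (any(tab$pos < 1)) stop(path, ": positions must be 1-based (>= 1)", call. = FALSE)
  lapply(split(tab, tab$contig), function(d) {
    n <- max(d$pos)
    male <- numeric(n)
    female <- numeric(n)
    male[d$pos] <- d$male
    female[d$pos] <- d$female
    depth_track(d$contig[1], male, female)
  })
}

#' Construct a depth track
#'
#' @param contig contig name
#' @param male_depth,female_depth non-negative per-position depth vectors of
#'   equal length (element `i` is 0-based position `i - 1`)
#' @return a `depth_track` object
#' @export
depth_track <- function(contig, male_depth, female_depth) {
  if (length(male_depth) != length(female_depth)) {
    stop("male and female depth vectors must have equal length", call. = FALSE)
  }
  if (any(male_depth < 0) || any(female_depth < 0)) {
    stop("depths must be non-negative", call. = FALSE)
  }
  structure(list(contig = contig, male_depth = as.numeric(male_depth),
                 female_depth = as.numeric(female_depth)),
            class = "depth_track")
}

#' Write a depth track as a 1-based 4-column TSV
#'
#' @param track a `depth_track`
#' @param path output file
#' @export
write_depth <- function(track, path) {
  stopifnot(inherits(track, "depth_track"))
  n <- length(track$male_depth)
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(
    data.frame(track$contig, seq_len(n), track$male_depth, track$female_depth),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    eol = "\n")
  invisible(path)
}

#' Write region calls as BED
#'
#' Standard BED (0-based half-open): contig, start, end, class name, score =
#' female read fraction x 1000 rounded.  Overlapping or adjacent calls of
#' the same class are merged before writing (score averaged, weighted by
#' length).
#'
#' @param calls data.frame of region calls (`contig`, `start`, `end`,
#'   `call`, `female_read_fraction`)
#' @param path output file
#' @export
write_bed <- function(calls, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(calls) == 0L) return(invisible(path))
  calls <- merge_region_calls(calls)
  score <- ifelse(is.na(calls$female_read_fraction), 0,
                  round(calls$female_read_fraction * 1000))
  utils::write.table(
    data.frame(calls$contig, calls$start, calls$end, calls$call, score),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    eol = "\n")
  invisible(path)
}

#' Read an expression matrix with sex and stage metadata
#'
#' Dialect: a tab-separated file whose first row holds `gene_id` plus the
#' sample ids, followed by two metadata rows labelled `#sex` (M/F per
#' sample) and `#stage` (stage label per sample), then one row per gene.
#'
#' @param path TSV file
#' @param unit `"counts"` or `"rpkm"` tag for the values
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path, unit = c("counts", "rpkm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop(path, ": expected sample, sex and stage header rows", call. = FALSE)
  split_row <- function(x) strsplit(x, "\t", fixed = TRUE)[[1]]
  hdr <- split_row(lines[1])
  sexrow <- split_row(lines[2])
  stagerow <- split_row(lines[3])
  if (sexrow[1] != "#sex" || stagerow[1] != "#stage") {
    stop(path, ": rows 2-3 must be '#sex' and '#stage' metadata rows", call. = FALSE)
  }
  sample_ids <- hdr[-1]
  sex <- sexrow[-1]
  stage <- stagerow[-1]
  if (length(sex) != length(sample_ids) || length(stage) != length(sample_ids)) {
    stop(path, ": metadata rows do not match the number of samples", call. = FALSE)
  }
  body <- utils::read.table(text = lines[-(1:3)], sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  values <- as.matrix(body[, -1, drop = FALSE])
  rownames(values) <- body[[1]]
  colnames(values) <- sample_ids
  expression_matrix(values, sex = sex, stage = stage, unit = unit)
}

#' Construct an expression matrix with sample metadata
#'
#' @param values non-negative numeric matrix, genes x samples
#' @param sex per-sample sex, `"M"` or `"F"`
#' @param stage per-sample stage label
#' @param unit `"counts"` or `"rpkm"`
#' @return an object of class `expression_matrix`
#' @export
expression_matrix <- function(values, sex, stage, unit = c("counts", "rpkm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (length(sex) != ncol(values) || length(stage) != ncol(values)) {
    stop("sex and stage must have one entry per sample", call. = FALSE)
  }
  if (any(values < 0)) stop("expression values must be non-negative", call. = FALSE)
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'", call. = FALSE)
  structure(list(values = values, sex = as.character(sex),
                 stage = as.character(stage), unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s), %d stages\n",
              nrow(x$values), ncol(x$values), x$unit, length(unique(x$stage))))
  invisible(x)
}

#' Write an expression matrix in the 2-metadata-row TSV dialect
#'
#' @param expr an [expression_matrix()]
#' @param path output file
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr$values)), collapse = "\t"), con)
  writeLines(paste(c("#sex", expr$sex), collapse = "\t"), con)
  writeLines(paste(c("#stage", expr$stage), collapse = "\t"), con)
  utils::write.table(
    data.frame(rownames(expr$values), expr$values, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    eol = "\n")
  invisible(path)
}

#' Read a gene coordinate / annotation table
#'
#' Minimal tab-separated gene table: `gene_id`, `contig`, `start`, `end`
#' (0-based half-open), `strand`, `is_te` (0/1 transposable-element flag,
#' supplied by the annotation, not recomputed).  A header row is required.
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "start", "end", "strand", "is_te")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(path, ": missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(tab$end <= tab$start)) stop(path, ": end must exceed start", call. = FALSE)
  tab$is_te <- as.logical(tab$is_te)
  tab
}
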