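# Readers/writers for BED, summit BED, narrowPeak, GTF, FASTA, chrom sizes.

#' Read a region file
#'
#' @param path file path.
#' @param dialect one of `"bed"` (3-6 columns), `"summit_bed"` (MACS2
#'   `_summits.bed`: 1-bp intervals whose start is the summit), or
#'   `"narrowpeak"` (ENCODE narrowPeak; column 10 is the 0-based summit
#'   offset from `start`, `-1` meaning "not determined", imputed as the
#'   region midpoint and flagged).
#' @param genome_id optional assembly label stored on the result.
#' @return a `region_set`.
#' @export
read_regions <- function(path, dialect = c("bed", "summit_bed", "narrowpeak"),
                         genome_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(region_set(genome_id = genome_id, provenance = path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- if (dialect == "narrowpeak") 10L else 3L
  nf <- lengths(fields)
  if (any(nf < ncol_min))
    stop("malformed line ", which(nf < ncol_min)[1], " in ", path,
         ": expected >= ", ncol_min, " fields")
  getcol <- function(k, default = NA) vapply(fields, function(f)
    if (length(f) >= k) f[k] else as.character(default), character(1))
  chrom <- getcol(1)
  start <- suppressWarnings(as.numeric(getcol(2)))
  end <- suppressWarnings(as.numeric(getcol(3)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path, ": bad coordinates")
  name <- getcol(4); name[name %in% c("NA", ".")] <- NA_character_
  score <- suppressWarnings(as.numeric(getcol(5)))
  summit <- rep(NA_real_, length(chrom))
  imputed <- rep(FALSE, length(chrom))
  if (dialect == "summit_bed") {
    summit <- start
  } else if (dialect == "narrowpeak") {
    off <- suppressWarnings(as.numeric(getcol(10)))
    if (anyNA(off)) stop("malformed narrowPeak summit column in ", path)
    summit <- ifelse(off >= 0, start + off, start + (end - start) %/% 2)
    imputed <- off < 0
  }
  region_set(chrom, start, end, name = name, score = score, summit = summit,
             summit_imputed = imputed, genome_id = genome_id,
             provenance = path)
}

#' Write a region set as BED
#'
#' Emits `chrom start end name score` (tab-separated, 0-based half-open);
#' missing names become `.` and missing scores `0`. Canonical records
#' round-trip byte-identically through [read_regions()].
#' @param rs a `region_set`.
#' @param path output path.
#' @param extra optional data.frame of extra columns appended verbatim.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path, extra = NULL) {
  nm <- ifelse(is.na(rs$name), ".", rs$name)
  sc <- ifelse(is.na(rs$score), "0", format(rs$score, trim = TRUE,
                                            scientific = FALSE))
  out <- paste(rs$chrom, format(rs$start, trim = TRUE, scientific = FALSE),
               format(rs$end, trim = TRUE, scientific = FALSE), nm, sc,
               sep = "\t")
  if (!is.null(extra))
    out <- paste(out, do.call(paste, c(unname(as.list(extra)), sep = "\t")),
                 sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses `gene` feature lines (1-based inclusive coordinates converted to
#' 0-based); extracts `gene_id`, `gene_name`, and `gene_biotype` attributes.
#' The TSS is the gene start on `+` and the last base on `-`.
#' @param path GTF file path.
#' @return a `gene_model` table.
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && any(nf < 9))
    stop("malformed GTF line ", which(nf < 9)[1], " in ", path)
  keep <- vapply(fields, function(f) f[3] == "gene", logical(1))
  fields <- fields[keep]
  if (!length(fields)) stop("no gene features in ", path)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start1 <- as.numeric(vapply(fields, `[`, character(1), 4))
  end1 <- as.numeric(vapply(fields, `[`, character(1), 5))
  strand <- vapply(fields, `[`, character(1), 7)
  attrs <- vapply(fields, `[`, character(1), 9)
  gid <- attr_get(attrs, "gene_id")
  gname <- attr_get(attrs, "gene_name"); gname[is.na(gname)] <- gid[is.na(gname)]
  biot <- attr_get(attrs, "gene_biotype")
  biot[is.na(biot)] <- "protein_coding"
  tss <- ifelse(strand == "+", start1 - 1, end1 - 1)
  gene_model(gid, gname, chrom, strand, tss, biot)
}

#' Write gene models as a minimal GTF
#'
#' One `gene` feature per row (1-based inclusive coordinates) with
#' `gene_id`, `gene_name`, and `gene_biotype` attributes. Genes are written
#' as 1 kb features anchored at the TSS (end-anchored on `-`).
#' @param genes a `gene_model` table.
#' @param path output path.
#' @param length_bp nominal gene length used for the feature span.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, length_bp = 1000) {
  start1 <- ifelse(genes$strand == "+", genes$tss + 1,
                   pmax(1, genes$tss + 1 - length_bp + 1))
  end1 <- ifelse(genes$strand == "+", genes$tss + length_bp, genes$tss + 1)
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                   genes$gene_id, genes$gene_name, genes$biotype)
  writeLines(paste(genes$chrom, "nrcobind", "gene", start1, end1, ".",
                   genes$strand, ".", attrs, sep = "\t"), path)
  invisible(path)
}

#' Read chromosome sizes
#'
#' Two-column (`name length`) tab-separated file, `.fai`-style (extra
#' columns ignored).
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return a named character vector of upper-case sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a genome FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Extract region sequences from a genome
#' @param seqs named character vector (from [read_genome()]).
#' @param rs a `region_set`; coordinates must fit inside the chromosomes.
#' @return character vector of sequences parallel to `rs`.
#' @export
region_sequences <- function(seqs, rs) {
  if (!all(rs$chrom %in% names(seqs)))
    stop("region chromosome absent from genome")
  len <- nchar(seqs)[rs$chrom]
  if (any(rs$end > len)) stop("region extends beyond chromosome end")
  substring(seqs[rs$chrom], rs$start + 1, rs$end)
}

#' Read a tab-separated counts table
#'
#' First column = feature id (region or gene), remaining columns = samples.
#' @param path file path.
#' @return numeric matrix with feature rownames.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a counts table
#' @param mat numeric matrix with rownames.
#' @param path output path.
#' @param id_col header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
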