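#' Construct a region set
#'
#' A `region_set` is the universal currency of the pipeline: an ordered
#' collection of genomic intervals in 0-based, half-open (BED) coordinates,
#' each optionally carrying a summit (single-base position of maximal
#' occupancy), a name, and a score.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param name optional region labels (recycled `NA` if absent).
#' @param score optional numeric scores.
#' @param summit optional 0-based summit positions, `start <= summit < end`.
#' @param summit_imputed logical; `TRUE` where a summit was imputed (e.g.
#'   midpoint substitution for a narrowPeak `-1` offset).
#' @param genome_id label of the assembly the coordinates refer to.
#' @param provenance free-text describing how the set was produced.
#' @param sort sort by `(chrom, start, end)` on construction (canonical form).
#'
#' @return An object of class `region_set`: a data.frame with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `summit`, `summit_imputed`
#'   and attributes `genome_id`, `provenance`.
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer(),
                       name = NULL, score = NULL, summit = NULL,
                       summit_imputed = NULL, genome_id = NA_character_,
                       provenance = NA_character_, sort = TRUE) {
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(end <= start)) stop("end must be strictly greater than start")
  if (is.null(name)) name <- rep(NA_character_, n)
  if (is.null(score)) score <- rep(NA_real_, n)
  if (is.null(summit)) summit <- rep(NA_real_, n)
  if (is.null(summit_imputed)) summit_imputed <- rep(FALSE, n)
  bad <- !is.na(summit) & (summit < start | summit >= end)
  if (any(bad)) stop("summit outside [start, end) for ", sum(bad), " region(s)")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), score = as.numeric(score),
                   summit = as.numeric(summit),
                   summit_imputed = as.logical(summit_imputed),
                   stringsAsFactors = FALSE)
  if (sort && n > 1) df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("region_set", "data.frame"),
            genome_id = genome_id, provenance = provenance)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set with %d region(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (!is.na(attr(x, "genome_id"))) cat("genome:", attr(x, "genome_id"), "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' @export
`[.region_set` <- function(x, i, j, ...) {
  if (!missing(j)) return(as.data.frame(x)[i, j, ...])
  df <- as.data.frame(x)[i, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("region_set", "data.frame"),
            genome_id = attr(x, "genome_id"),
            provenance = attr(x, "provenance"))
}

rs_from_df <- function(df, template = NULL, sort = TRUE) {
  region_set(df$chrom, df$start, df$end, name = df$name, score = df$score,
             summit = df$summit, summit_imputed = df$summit_imputed,
             genome_id = if (is.null(template)) NA_character_ else
               attr(template, "genome_id"),
             provenance = if (is.null(template)) NA_character_ else
               attr(template, "provenance"),
             sort = sort)
}

#' Canonicalize a region set
#'
#' Sorts by `(chrom, start, end)` and drops exact duplicates of
#' `(chrom, start, end, name)`.
#' @param rs a `region_set`.
#' @return the canonicalized `region_set`.
#' @export
canonicalize <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  key <- paste(rs$chrom, rs$start, rs$end, rs$name, sep = "\r")
  rs_from_df(as.data.frame(rs)[!duplicated(key), , drop = FALSE],
             template = rs, sort = TRUE)
}

#' Region midpoints
#'
#' Center of a half-open interval: `start + (end - start) %/% 2`. For a
#' symmetric summit +/- flank region this reproduces the summit exactly.
#' @param rs a `region_set`.
#' @return numeric vector of 0-based center positions.
#' @export
region_center <- function(rs) rs$start + (rs$end - rs$start) %/% 2

#' Gene model table
#'
#' @param gene_id,gene_name,chrom,strand,tss,biotype vectors of equal length;
#'   `strand` must be `+` or `-`; `tss` 0-based. On the `+` strand the TSS is
#'   the gene start, on `-` the last base (`end - 1`).
#' @return data.frame of class `gene_model`.
#' @export
gene_model <- function(gene_id, gene_name = gene_id, chrom, strand, tss,
                       biotype = "protein_coding") {
  stopifnot(all(strand %in% c("+", "-")))
  df <- data.frame(gene_id = as.character(gene_id),
                   gene_name = as.character(gene_name),
                   chrom = as.character(chrom), strand = as.character(strand),
                   tss = as.numeric(tss), biotype = as.character(biotype),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_model", "data.frame")
  df
}
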