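# Readers, validators and writers for the standard input/output tables.
#
# Conventions: BED/BEDPE-like interval inputs are 0-based half-open; point
# positions (GWAS variants, gene TSS) are 1-based. Gene identity is by
# case-sensitive symbol; no alias resolution is attempted.

.stop_schema <- function(path, missing) {
  stop(sprintf("file '%s' is missing required column(s): %s",
               path, paste(missing, collapse = ", ")), call. = FALSE)
}

.check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) .stop_schema(path, missing)
  invisible(df)
}

.bad_rows <- function(ok, what, path) {
  if (any(!ok)) {
    idx <- which(!ok)
    stop(sprintf("invalid %s in '%s' at row(s): %s", what, path,
                 paste(head(idx, 5L), collapse = ", ")), call. = FALSE)
  }
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, quote = "")
}

#' Read GWAS summary statistics
#'
#' Expects a TSV with columns `variant_id`, `chromosome`, `position`
#' (1-based bp) and `pvalue`. Variant identifiers must be unique and
#' p-values strictly in (0, 1].
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `data.frame` with the four validated columns.
#' @export
read_gwas <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("variant_id", "chromosome", "position", "pvalue"), path)
  df$variant_id <- as.character(df$variant_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df$pvalue <- as.numeric(df$pvalue)
  validate_variant_table(df, path)
  df[, c("variant_id", "chromosome", "position", "pvalue")]
}

#' @rdname read_gwas
#' @param df A data.frame to validate in place of a file.
#' @export
validate_variant_table <- function(df, path = "<in-memory>") {
  if (anyDuplicated(df$variant_id))
    stop(sprintf("duplicate variant_id in '%s'", path), call. = FALSE)
  .bad_rows(!is.na(df$position) & df$position >= 1L, "position (must be >= 1)", path)
  .bad_rows(!is.na(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1,
            "pvalue (must be in (0,1])", path)
  invisible(df)
}

#' Read a gene annotation (TSS) table
#'
#' Expects BED-like columns `gene`, `chromosome`, `tss` (1-based bp) and
#' `strand` (`+`/`-`). Strand is carried only to define the TSS; distances
#' are unsigned.
#'
#' @inheritParams read_gwas
#' @return A validated `data.frame`.
#' @export
read_gene_annotation <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("gene", "chromosome", "tss", "strand"), path)
  df$gene <- as.character(df$gene)
  df$chromosome <- as.character(df$chromosome)
  df$tss <- as.integer(df$tss)
  df$strand <- as.character(df$strand)
  if (anyDuplicated(df$gene))
    stop(sprintf("duplicate gene in '%s'", path), call. = FALSE)
  .bad_rows(!is.na(df$tss) & df$tss >= 1L, "tss (must be >= 1)", path)
  .bad_rows(df$strand %in% c("+", "-"), "strand (must be + or -)", path)
  df[, c("gene", "chromosome", "tss", "strand")]
}

#' Read a linkage-disequilibrium pair table
#'
#' Expects columns `variant_a`, `variant_b`, `r2` with r-squared in
#' \[0, 1\]. Pairs are undirected; both orientations are accepted.
#'
#' @inheritParams read_gwas
#' @return A validated `data.frame`.
#' @export
read_ld_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("variant_a", "variant_b", "r2"), path)
  df$variant_a <- as.character(df$variant_a)
  df$variant_b <- as.character(df$variant_b)
  df$r2 <- as.numeric(df$r2)
  .bad_rows(!is.na(df$r2) & df$r2 >= 0 & df$r2 <= 1, "r2 (must be in [0,1])", path)
  df[, c("variant_a", "variant_b", "r2")]
}

#' Read promoter-capture Hi-C links
#'
#' Expects BEDPE-like columns `fragment_chrom`, `fragment_start`,
#' `fragment_end` (0-based half-open), `gene` and `link_score` (>= 0).
#'
#' @inheritParams read_gwas
#' @return A validated `data.frame`.
#' @export
read_hic_links <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("fragment_chrom", "fragment_start", "fragment_end",
                       "gene", "link_score"), path)
  df$fragment_chrom <- as.character(df$fragment_chrom)
  df$fragment_start <- as.integer(df$fragment_start)
  df$fragment_end <- as.integer(df$fragment_end)
  df$gene <- as.character(df$gene)
  df$link_score <- as.numeric(df$link_score)
  .bad_rows(!is.na(df$fragment_start) & !is.na(df$fragment_end) &
              df$fragment_start < df$fragment_end,
            "fragment interval (start must be < end)", path)
  .bad_rows(!is.na(df$link_score) & df$link_score >= 0,
            "link_score (must be >= 0)", path)
  df[, c("fragment_chrom", "fragment_start", "fragment_end", "gene", "link_score")]
}

#' Read eQTL variant-to-gene links
#'
#' Expects columns `variant_id`, `gene`, `eqtl_pvalue` with p-values in
#' (0, 1].
#'
#' @inheritParams read_gwas
#' @return A validated `data.frame`.
#' @export
read_eqtl_links <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("variant_id", "gene", "eqtl_pvalue"), path)
  df$variant_id <- as.character(df$variant_id)
  df$gene <- as.character(df$gene)
  df$eqtl_pvalue <- as.numeric(df$eqtl_pvalue)
  .bad_rows(!is.na(df$eqtl_pvalue) & df$eqtl_pvalue > 0 & df$eqtl_pvalue <= 1,
            "eqtl_pvalue (must be in (0,1])", path)
  df[, c("variant_id", "gene", "eqtl_pvalue")]
}

#' Read a protein-protein interaction edge list
#'
#' Expects columns `gene_a`, `gene_b` and optionally `weight` (> 0).
#' Self-loops and duplicate edges are rejected. Returns an undirected
#' [igraph::igraph] with gene symbols as vertex names.
#'
#' @inheritParams read_gwas
#' @return An undirected simple `igraph` graph.
#' @export
read_ppi_network <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("gene_a", "gene_b"), path)
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  .bad_rows(df$gene_a != df$gene_b, "edge (self-loops not allowed)", path)
  key <- paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
  .bad_rows(!duplicated(key), "edge (duplicate edges not allowed)", path)
  if ("weight" %in% names(df)) {
    df$weight <- as.numeric(df$weight)
    .bad_rows(!is.na(df$weight) & df$weight > 0, "weight (must be > 0)", path)
    g <- igraph::graph_from_data_frame(df[, c("gene_a", "gene_b", "weight")],
                                       directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(df[, c("gene_a", "gene_b")],
                                       directed = FALSE)
  }
  g
}

#' Read a drug-target annotation table
#'
#' Expects columns `gene`, `drug`, `max_phase` (integer 0-4), `mechanism`
#' and `indication`.
#'
#' @inheritParams read_gwas
#' @return A validated `data.frame`.
#' @export
read_drug_targets <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("gene", "drug", "max_phase", "mechanism", "indication"), path)
  df$gene <- as.character(df$gene)
  df$drug <- as.character(df$drug)
  df$max_phase <- as.integer(df$max_phase)
  df$mechanism <- as.character(df$mechanism)
  df$indication <- as.character(df$indication)
  .bad_rows(!is.na(df$max_phase) & df$max_phase >= 0L & df$max_phase <= 4L,
            "max_phase (must be an integer in 0..4)", path)
  df[, c("gene", "drug", "max_phase", "mechanism", "indication")]
}

#' Read a GMT gene-set collection
#'
#' GMT dialect: `name TAB description TAB gene1 TAB gene2 ...`, one set per
#' line. Duplicate genes within a line are deduplicated; duplicate set
#' names are an error.
#'
#' @inheritParams read_gwas
#' @return A named list of character vectors; descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning(sprintf("GMT file '%s' is empty", path))
    sets <- list()
    attr(sets, "descriptions") <- character(0)
    return(sets)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("GMT parse error in '%s' at line %d: fewer than 3 fields",
                 path, which(nf < 3L)[1L]), call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop(sprintf("duplicate gene-set name in '%s': %s", path, dup[1L]),
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets
}

# Format numeric columns to 10 significant digits so that write/read round
# trips are exact at the documented precision and reruns are byte-identical.
.format_table <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.10g", col) else col
  })
  df
}

#' Write result tables and a run manifest
#'
#' Writes each table in `tables` as `<name>.tsv` under `out_dir` (reals at
#' 10 significant digits, so a rerun with identical inputs is
#' byte-identical) and a `manifest.yaml` recording the seed, all supplied
#' parameters and MD5 checksums of input and output files.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory, created if absent.
#' @param seed Integer seed used for the run (recorded, not consumed).
#' @param params Named list of run parameters to record.
#' @param inputs Optional character vector of input file paths to checksum.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, seed = NULL, params = list(),
                          inputs = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  written <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(.format_table(tables[[nm]]), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = TRUE, eol = "\n")
    written[nm] <- path
  }
  out_md5 <- tools::md5sum(written)
  names(out_md5) <- names(written)
  manifest <- list(
    seed = seed,
    parameters = params,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    outputs = as.list(out_md5)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
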