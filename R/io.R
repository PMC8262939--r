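#' Table schemas for the annotation and statistics inputs
#'
#' Returns the declared schema for one of the package's table dialects: the
#' required columns, their types and the row-level invariants enforced by
#' [read_validated()].
#'
#' @param name one of `"proteins"`, `"domain_hits"`, `"alignment_hits"`,
#'   `"isolates"`, `"genus"`.
#' @return A list with `columns` (named character vector of types) and
#'   `check` (a function mapping a data frame to a character vector of
#'   row-level problems, empty when clean).
#' @export
table_schema <- function(name = c("proteins", "domain_hits",
                                  "alignment_hits", "isolates", "genus")) {
  name <- match.arg(name)
  schemas <- list(
    proteins = list(
      columns = c(protein_id = "character", genome_id = "character",
                  contig_id = "character", gene_start = "integer",
                  gene_end = "integer", strand = "character",
                  length = "integer"),
      check = function(d) {
        probs <- character(0)
        bad <- which(d$gene_start > d$gene_end)
        if (length(bad)) probs <- c(probs, paste0(
          "row ", bad, ": gene_start > gene_end"))
        bad <- which(d$length <= 0)
        if (length(bad)) probs <- c(probs, paste0("row ", bad, ": length <= 0"))
        probs
      }),
    domain_hits = list(
      columns = c(protein_id = "character", profile_id = "character",
                  env_start = "integer", env_end = "integer",
                  evalue = "numeric", role = "character"),
      check = function(d) {
        probs <- character(0)
        bad <- which(d$env_start > d$env_end)
        if (length(bad)) probs <- c(probs, paste0(
          "row ", bad, ": env_start > env_end"))
        bad <- which(d$evalue < 0)
        if (length(bad)) probs <- c(probs, paste0("row ", bad, ": evalue < 0"))
        probs
      }),
    alignment_hits = list(
      columns = c(protein_id = "character", query_id = "character",
                  query_length = "integer", align_length = "integer",
                  evalue = "numeric", role = "character"),
      check = function(d) {
        probs <- character(0)
        bad <- which(d$query_length <= 0 | d$align_length <= 0)
        if (length(bad)) probs <- c(probs, paste0(
          "row ", bad, ": non-positive alignment length"))
        probs
      }),
    isolates = list(
      columns = c(assembly_id = "character", genus = "character",
                  genome_size = "numeric", rm_total = "numeric"),
      check = function(d) {
        probs <- character(0)
        bad <- which(d$genome_size <= 0)
        if (length(bad)) probs <- c(probs, paste0(
          "row ", bad, ": genome_size <= 0"))
        bad <- which(d$rm_total < 0)
        if (length(bad)) probs <- c(probs, paste0("row ", bad, ": rm_total < 0"))
        probs
      }),
    genus = list(
      columns = c(genus = "character", n_isolates = "integer",
                  mean_rmpg = "numeric", mean_genome_size = "numeric"),
      check = function(d) {
        probs <- character(0)
        bad <- which(d$n_isolates < 1)
        if (length(bad)) probs <- c(probs, paste0(
          "row ", bad, ": n_isolates < 1"))
        probs
      })
  )
  schemas[[name]]
}

#' Read and validate a delimited table against a declared schema
#'
#' Parses a CSV or TSV file (dialect inferred from the extension, or set via
#' `sep`), coerces columns to the schema's types, and enforces the schema's
#' row invariants. In strict mode (default) any violation aborts with the
#' offending row numbers; in lenient mode violating rows are dropped with a
#' warning.
#'
#' @param path file path.
#' @param schema a schema name accepted by [table_schema()], or a schema
#'   list of the same shape.
#' @param strict abort on invalid rows (`TRUE`) or drop them (`FALSE`).
#' @param sep field separator; `NULL` infers `","` for `.csv` and `"\t"`
#'   otherwise.
#' @return The validated data frame.
#' @export
read_validated <- function(path, schema, strict = TRUE, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.character(schema)) schema <- table_schema(schema)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, quote = "\"",
                         comment.char = "")
  missing <- setdiff(names(schema$columns), names(d))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in names(schema$columns)) {
    d[[col]] <- switch(schema$columns[[col]],
                       character = as.character(d[[col]]),
                       integer = as.integer(d[[col]]),
                       numeric = as.numeric(d[[col]]))
  }
  probs <- schema$check(d)
  if (length(probs)) {
    if (strict) {
      stop("invalid rows in ", path, ":\n  ",
           paste(utils::head(probs, 10), collapse = "\n  "))
    }
    bad_rows <- unique(as.integer(sub("^row ([0-9]+):.*$", "\\1", probs)))
    warning("dropping ", length(bad_rows), " invalid row(s) from ", path)
    d <- d[-bad_rows, , drop = FALSE]
  }
  d
}

#' Write a table in the package's delimited dialect
#'
#' UTF-8, header row, `.` decimal separator; the separator follows the file
#' extension (`,` for `.csv`, tab otherwise).
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an experiment configuration file
#'
#' YAML configurations hold the model kind, community structure, parameter
#' values or ranges, supply grid and seeds of an experiment. Unknown keys
#' are preserved; a few known numeric fields are validated.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$kind) &&
      !cfg$kind %in% c("general", "parallel", "memory")) {
    stop("config: unknown model kind '", cfg$kind, "'")
  }
  if (!is.null(cfg$arrangement) &&
      !cfg$arrangement %in% c("subset", "unique")) {
    stop("config: unknown arrangement '", cfg$arrangement, "'")
  }
  if (!is.null(cfg$S_grid)) {
    cfg$S_grid <- as.numeric(cfg$S_grid)
    if (is.unsorted(cfg$S_grid, strictly = TRUE)) {
      stop("config: S_grid must be strictly increasing")
    }
  }
  cfg
}

#' Reproducibility manifest for an experiment run
#'
#' @param config the configuration list used.
#' @param seed the root seed.
#' @return A list recording the package version, seed and a digest-free
#'   canonical dump of the configuration, suitable for writing alongside
#'   outputs.
#' @export
run_manifest <- function(config, seed) {
  list(package = "rmdefense",
       version = as.character(utils::packageVersion("rmdefense")),
       seed = seed,
       config = config)
}
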