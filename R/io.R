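# File formats: SEG (1-based inclusive externally, 0-based half-open
# internally), schema-validated TSV tables, and the run manifest.

#' Read a SEG file
#'
#' Expects the standard columns `ID`, `chrom`, `loc.start`, `loc.end`
#' (1-based inclusive), optional `num.mark`, and `seg.mean` (header names
#' are matched case-insensitively and tolerantly). Chromosome names are
#' normalized ("chr17" and "17" are equivalent); coordinates are converted
#' to 0-based half-open internally.
#'
#' @param path Path to a tab-separated SEG file.
#' @return Named list of `segment_profile`s, one per sample.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  cols <- tolower(gsub("[._ ]", "", names(df)))
  pick <- function(keys) {
    i <- which(cols %in% keys)
    if (length(i) == 0)
      stop("SEG file ", path, " is missing a required column (",
           paste(keys, collapse = "/"), ")")
    df[[i[1]]]
  }
  id <- as.character(pick(c("id", "sample", "sampleid")))
  chrom <- sub("^chr", "", as.character(pick(c("chrom", "chromosome"))))
  start <- pick(c("locstart", "start"))
  end <- pick(c("locend", "end"))
  segmean <- pick(c("segmean", "mean", "logr"))
  nm_i <- which(cols %in% c("nummark", "numprobes", "markers"))
  n_probes <- if (length(nm_i)) df[[nm_i[1]]] else NA_integer_
  num <- list(start = start, end = end, segmean = segmean)
  for (nm in names(num)) {
    v <- suppressWarnings(as.numeric(num[[nm]]))
    if (anyNA(v))
      stop("unparseable numeric field '", nm, "' in ", path, " at line(s) ",
           paste(utils::head(which(is.na(v)) + 1, 3), collapse = ", "))
    num[[nm]] <- v
  }
  out <- lapply(split(seq_len(nrow(df)), id), function(idx) {
    prof <- try(segment_profile(id[idx[1]], chrom[idx],
                                num$start[idx] - 1, num$end[idx],
                                num$segmean[idx],
                                if (all(is.na(n_probes))) NA_integer_
                                else n_probes[idx]),
                silent = TRUE)
    if (inherits(prof, "try-error"))
      stop("sample ", id[idx[1]], " in ", path, " (lines ",
           paste(range(idx + 1), collapse = "-"), "): ",
           attr(prof, "condition")$message)
    prof
  })
  out[order(names(out))]
}

#' Write segment profiles as a SEG file
#'
#' Internal 0-based half-open coordinates are converted back to 1-based
#' inclusive.
#'
#' @param profiles A `segment_profile` or list of them.
#' @param path Output path.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(ID = attr(p, "sample_id"), chrom = p$chrom,
               loc.start = p$start + 1, loc.end = p$end,
               num.mark = p$n_probes, seg.mean = p$seg_mean,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Schemas for the tabular inputs; each entry: required columns -> type.
.table_schemas <- list(
  survival = c(sample = "character", time = "numeric", event = "integer"),
  mutations = c(sample = "character", gene = "character",
                variant_class = "character"),
  expression = NULL, # genes x samples matrix, handled separately
  growth = c(time = "numeric", count = "numeric")
)

# MAF-dialect column aliases accepted on input.
.column_aliases <- c(
  Tumor_Sample_Barcode = "sample", Hugo_Symbol = "gene",
  Variant_Classification = "variant_class", HGVSp_Short = "protein_change"
)

#' Read a typed TSV table
#'
#' Validates required columns and coerces types according to a named
#' schema; extra columns are preserved untouched. Standard MAF column
#' names (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`,
#' `HGVSp_Short`) are renamed to the internal names.
#'
#' @param path Path to a TSV file with a header.
#' @param schema One of `"survival"`, `"mutations"`, `"growth"`, or a
#'   named character vector mapping required columns to types
#'   (`"character"`, `"numeric"`, `"integer"`).
#' @return Data frame with validated columns.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1) {
    if (!schema %in% names(.table_schemas) || is.null(.table_schemas[[schema]]))
      stop("unknown schema: ", schema)
    schema <- .table_schemas[[schema]]
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  hit <- names(df) %in% names(.column_aliases)
  names(df)[hit] <- .column_aliases[names(df)[hit]]
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in names(schema)) {
    v <- switch(schema[[col]],
                character = as.character(df[[col]]),
                numeric = suppressWarnings(as.numeric(df[[col]])),
                integer = suppressWarnings(as.integer(df[[col]])))
    if (schema[[col]] != "character" && anyNA(v) && !anyNA(df[[col]]))
      stop("column '", col, "' in ", path, " cannot be coerced to ",
           schema[[col]])
    df[[col]] <- v
  }
  df
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column (or row names) holds gene ids; remaining columns are
#' samples.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  genes <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "numeric"
  if (anyNA(mat)) stop("expression matrix contains missing values")
  rownames(mat) <- genes
  mat
}

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version, input and
#' output file digests (md5) and a timestamp, so a run can be reproduced
#' exactly.
#'
#' @param path Output JSON path.
#' @param config Configuration list to snapshot.
#' @param seed Integer seed used for the run.
#' @param files Character vector of input/output paths to digest.
#' @export
write_manifest <- function(path, config, seed, files = character(0)) {
  digest <- vapply(files, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  manifest <- list(
    package = "aneuploidr",
    version = as.character(utils::packageVersion("aneuploidr")),
    seed = seed, config = config,
    files = as.list(digest),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a YAML or JSON configuration file
#' @param path Path ending in .yaml/.yml or .json.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
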