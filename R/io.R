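## Matrisome category -> division mapping used for validation throughout.
.matrisomeCategories <- c(
  "ECM glycoproteins"       = "core matrisome",
  "collagens"               = "core matrisome",
  "proteoglycans"           = "core matrisome",
  "ECM-affiliated proteins" = "matrisome-associated",
  "ECM regulators"          = "matrisome-associated",
  "secreted factors"        = "matrisome-associated"
)

#' Write and read a count matrix as a MatrixMarket triple
#'
#' `writeCountsMTX()` writes `matrix.mtx` (genes as rows, 1-based
#' coordinates, 10x convention), `features.tsv`, `barcodes.tsv` and
#' `cells.tsv` (barcode, compartment, donor) into `dir`.
#' `readCountsMTX()` reads them back into a
#' [SingleCellExperiment::SingleCellExperiment]; the pair is an identity on
#' values and labels. All-zero genes survive the round trip because the
#' feature file fixes the row dimension.
#'
#' @param sce a `SingleCellExperiment` with assay `counts` and `colData`
#'   columns `compartment`, `donor`.
#' @param dir directory for the triple (created if missing).
#' @return `readCountsMTX`: a `SingleCellExperiment`; `writeCountsMTX`:
#'   `dir`, invisibly.
#' @name counts-mtx
NULL

#' @rdname counts-mtx
#' @export
writeCountsMTX <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "features.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  write.table(data.frame(barcode = colnames(sce),
                         compartment = cd$compartment, donor = cd$donor),
              file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname counts-mtx
#' @export
readCountsMTX <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "cells.tsv"))
  names(paths) <- basename(paths)
  for (p in paths[1:3]) if (!file.exists(p)) stopf("missing file: %s", p)
  m <- tryCatch(Matrix::readMM(paths[["matrix.mtx"]]),
                error = function(e) stopf("matrix.mtx: invalid MatrixMarket file (%s)",
                                          conditionMessage(e)))
  ## readMM tolerates some malformed coordinate input; re-check bounds
  if (any(m@i < 0L)) stopf("matrix.mtx: coordinate out of bounds")
  genes <- readLines(paths[["features.tsv"]])
  ## 10x-style feature files may carry extra tab-separated columns
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
  cells <- readLines(paths[["barcodes.tsv"]])
  if (nrow(m) != length(genes)) {
    stopf("features.tsv: %d features but matrix.mtx has %d rows",
          length(genes), nrow(m))
  }
  if (ncol(m) != length(cells)) {
    stopf("barcodes.tsv: %d barcodes but matrix.mtx has %d columns",
          length(cells), ncol(m))
  }
  if (anyDuplicated(canonicalizeSymbols(genes))) {
    stopf("features.tsv: duplicate gene symbols after canonicalization")
  }
  dense <- as.matrix(m)
  if (any(dense < 0) || any(dense != round(dense))) {
    stopf("matrix.mtx: counts must be non-negative integers")
  }
  storage.mode(dense) <- "integer"
  dimnames(dense) <- list(genes, cells)
  cd <- S4Vectors::DataFrame(row.names = cells)
  if (file.exists(paths[["cells.tsv"]])) {
    meta <- read.delim(paths[["cells.tsv"]], stringsAsFactors = FALSE)
    need <- c("barcode", "compartment", "donor")
    if (!all(need %in% names(meta))) {
      stopf("cells.tsv: expected columns %s", paste(need, collapse = ", "))
    }
    if (!setequal(meta$barcode, cells)) {
      stopf("cells.tsv: barcodes do not match barcodes.tsv")
    }
    meta <- meta[match(cells, meta$barcode), ]
    if (!all(meta$compartment %in% c("AF", "NP"))) {
      stopf("cells.tsv: compartment labels must be 'AF' or 'NP'")
    }
    cd <- S4Vectors::DataFrame(compartment = meta$compartment,
                               donor = meta$donor, row.names = cells)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = dense), colData = cd)
}

#' Read and write GMT gene-set files
#'
#' GMT lines are tab-separated: set name, description, then member symbols.
#' Lines with fewer than three fields and duplicate set names are format
#' errors; duplicate members within a set are dropped with a warning.
#'
#' @param path file path.
#' @param sets named list of character vectors; descriptions taken from the
#'   `"descriptions"` attribute when present.
#' @return `readGMT`: named list of member vectors with a `"descriptions"`
#'   attribute; `writeGMT`: `path`, invisibly.
#' @name gmt-io
NULL

#' @rdname gmt-io
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stopf("%s: line %d has fewer than 3 tab-separated fields",
          path, short[1L])
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stopf("%s: duplicate set name '%s'", path, nm[duplicated(nm)][1L])
  }
  sets <- lapply(parts, function(p) {
    mem <- p[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (anyDuplicated(mem)) {
      warning(sprintf("set '%s': %d duplicate members dropped",
                      p[1L], sum(duplicated(mem))), call. = FALSE)
      mem <- unique(mem)
    }
    mem
  })
  names(sets) <- nm
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' @rdname gmt-io
#' @export
writeGMT <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style interaction table
#'
#' Expects a headered TSV with columns `gene_a`, `gene_b`,
#' `combined_score`. Pairs are canonicalized to undirected lexicographic
#' order, duplicates collapsed keeping the maximum score, and self-loops
#' dropped with a message. Scores may be on the `[0,1]` or `[0,1000]`
#' STRING dialect; values above 1 are divided by 1000 with a message.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `gene_a`, `gene_b`, `combined_score`
#'   (in `[0,1]`), one row per unordered pair.
#' @export
readInteractions <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(tab))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  tab$combined_score <- numericColumn(tab$combined_score, "combined_score",
                                      path)
  cleanInteractions(tab, source = path)
}

## shared cleaning for interaction tables, whether read or simulated
cleanInteractions <- function(tab, source = "interaction table") {
  if (nrow(tab) == 0L) return(tab)
  if (any(tab$combined_score < 0)) {
    stopf("%s: combined_score must be >= 0", source)
  }
  if (any(tab$combined_score > 1)) {
    if (any(tab$combined_score > 1000)) {
      stopf("%s: combined_score outside [0,1] and [0,1000]", source)
    }
    msgf("%s: scores on the 0-1000 STRING scale; dividing by 1000", source)
    tab$combined_score <- tab$combined_score / 1000
  }
  a <- canonicalizeSymbols(tab$gene_a)
  b <- canonicalizeSymbols(tab$gene_b)
  self <- a == b
  if (any(self)) {
    msgf("%s: dropped %d self-interaction(s)", source, sum(self))
    tab <- tab[!self, , drop = FALSE]; a <- a[!self]; b <- b[!self]
  }
  ga <- pmin(a, b); gb <- pmax(a, b)
  out <- data.frame(gene_a = ga, gene_b = gb,
                    combined_score = tab$combined_score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, -out$combined_score), ]
  out <- out[!duplicated(out[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write differential-expression tables
#'
#' A DE table is a headered TSV with at least columns `gene`, `logFC`, `p`
#' (optionally `q`); numeric columns are validated, not silently coerced.
#'
#' @param path TSV file path.
#' @param tab a DE `data.frame` to write.
#' @return `readDETable`: a typed `data.frame`; `writeDETable`: `path`,
#'   invisibly.
#' @name detable-io
NULL

#' @rdname detable-io
#' @export
readDETable <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "logFC", "p")
  if (!all(need %in% names(tab))) {
    stopf("%s: expected columns %s (found: %s)", path,
          paste(need, collapse = ", "), paste(names(tab), collapse = ", "))
  }
  tab$gene <- canonicalizeSymbols(tab$gene)
  tab$logFC <- numericColumn(tab$logFC, "logFC", path)
  tab$p <- numericColumn(tab$p, "p", path)
  if ("q" %in% names(tab)) tab$q <- numericColumn(tab$q, "q", path)
  tab
}

#' @rdname detable-io
#' @export
writeDETable <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrisome-style category table
#'
#' Headered TSV with columns `gene`, `division`, `category`; one row per
#' gene. The division must be consistent with the category (core matrisome:
#' ECM glycoproteins, collagens, proteoglycans; matrisome-associated:
#' ECM-affiliated proteins, ECM regulators, secreted factors).
#'
#' @param path TSV file path.
#' @return typed `data.frame` with canonical gene symbols.
#' @export
readCategoryTable <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "division", "category")
  if (!all(need %in% names(tab))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  tab$gene <- canonicalizeSymbols(tab$gene)
  if (anyDuplicated(tab$gene)) {
    stopf("%s: duplicate gene '%s'", path, tab$gene[duplicated(tab$gene)][1L])
  }
  validateCategories(tab, source = path)
  tab
}

validateCategories <- function(tab, source = "category table") {
  unknown <- setdiff(tab$category, names(.matrisomeCategories))
  if (length(unknown) > 0L) {
    stopf("%s: unknown category '%s'", source, unknown[1L])
  }
  expect <- unname(.matrisomeCategories[tab$category])
  bad <- which(tab$division != expect)
  if (length(bad) > 0L) {
    stopf("%s: gene %s has category '%s' but division '%s'",
          source, tab$gene[bad[1L]], tab$category[bad[1L]],
          tab$division[bad[1L]])
  }
  invisible(tab)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of canonical symbols, de-duplicated.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  x <- canonicalizeSymbols(readLines(path))
  unique(x[nzchar(x)])
}

#' Read a regulon table (TF, target, NES)
#'
#' Headered TSV with columns `tf`, `target`, `nes`; NES must be finite and
#' (tf, target) pairs unique.
#'
#' @param path TSV file path.
#' @return typed `data.frame`.
#' @export
readRegulons <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "nes")
  if (!all(need %in% names(tab))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  tab$tf <- canonicalizeSymbols(tab$tf)
  tab$target <- canonicalizeSymbols(tab$target)
  tab$nes <- numericColumn(tab$nes, "nes", path)
  if (any(!is.finite(tab$nes))) stopf("%s: non-finite NES value", path)
  if (anyDuplicated(tab[, c("tf", "target")])) {
    stopf("%s: duplicate (tf, target) pair", path)
  }
  tab
}
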