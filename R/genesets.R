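#' Construct a gene-set collection
#'
#' A collection of named gene sets, optionally annotated with a category
#' (`"predictor"`, `"function"`, `"cell_type"` or `"unknown"`) and a free-text
#' description.  Collections are the unit handled by [read_gmt()],
#' [score_signatures()] and the discovery pipeline.
#'
#' @param sets named list of character vectors of gene identifiers. Genes are
#'   de-duplicated within a set preserving first occurrence; empty sets are an
#'   error, as are duplicated set names.
#' @param category optional character vector (recycled) of per-set categories.
#' @param description optional character vector of per-set descriptions.
#' @return An object of class `iges_genesets`: the named list of gene vectors
#'   with `category` and `description` attributes.
#' @examples
#' gs <- gene_sets(list(A = c("g1", "g2"), B = c("g3", "g4", "g5")))
#' length(gs)
#' @export
gene_sets <- function(sets, category = NULL, description = NULL) {
  stopifnot(is.list(sets))
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || any(!nzchar(nm)))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    g[!duplicated(g)]
  })
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  category <- rep_len(if (is.null(category)) "unknown" else category,
                      length(sets))
  description <- rep_len(if (is.null(description)) "" else description,
                         length(sets))
  names(category) <- names(description) <- nm
  structure(sets, category = category, description = description,
            class = "iges_genesets")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields are name, description,
#' then one gene per field.  Duplicate genes within a line are dropped keeping
#' the first occurrence.
#'
#' @param path path to a GMT file.
#' @return An [gene_sets()] collection (empty file gives an empty collection).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gene_sets(structure(list(), names = character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                 bad[1]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g[nzchar(g)]
  })
  names(sets) <- nm
  gene_sets(sets, description = desc)
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets an `iges_genesets` collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "iges_genesets"))
  desc <- attr(sets, "description")
  lines <- vapply(seq_along(sets), function(i) {
    d <- desc[[i]]
    if (!nzchar(d)) d <- "na"
    paste(c(names(sets)[i], d, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.iges_genesets <- function(x, ...) {
  cat(sprintf("Gene set collection: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))))
  cats <- table(attr(x, "category"))
  cat("Categories:", paste(sprintf("%s=%d", names(cats), cats), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
`[.iges_genesets` <- function(x, i) {
  sets <- unclass(x)[i]
  gene_sets(sets,
            category = attr(x, "category")[names(sets)],
            description = attr(x, "description")[names(sets)])
}
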