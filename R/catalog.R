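#' Construct a gene set
#'
#' A gene set is a named collection of gene symbols with a category label.
#' Symbols are uppercased and deduplicated; matching elsewhere in the package
#' is case-insensitive after uppercasing (no alias resolution is attempted).
#'
#' @param name Non-empty set name.
#' @param genes Character vector of gene symbols (non-empty).
#' @param category One of `"oncogenic"`, `"ddr"`, `"other"`.
#' @param description Free-text description (kept for GMT round-trips).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, category = c("other", "oncogenic", "ddr"),
                     description = "") {
  category <- match.arg(category)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a non-empty string")
  genes <- toupper(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    stop("gene set '", name, "' has no genes")
  if (anyDuplicated(genes))
    genes <- unique(genes)
  structure(
    list(name = name, category = category, genes = genes,
         description = description),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s], %d genes\n", x$name, x$category,
              length(x$genes)))
  invisible(x)
}

#' Construct a pathway catalog
#'
#' An ordered collection of [gene_set()] objects with unique names, plus a
#' provenance string recording where the gene membership came from.
#'
#' @param sets List of `gene_set` objects.
#' @param provenance Free-text provenance.
#' @return An object of class `pathway_catalog`.
#' @export
pathway_catalog <- function(sets, provenance = "") {
  stopifnot(is.list(sets))
  if (length(sets) && !all(vapply(sets, inherits, logical(1), "gene_set")))
    stop("all elements of 'sets' must be gene_set objects")
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate set names in catalog: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(list(sets = sets, provenance = provenance),
            class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cats <- table(factor(vapply(x$sets, function(s) s$category, character(1)),
                       levels = c("oncogenic", "ddr", "other")))
  cat(sprintf("<pathway_catalog> %d sets (%d oncogenic, %d ddr, %d other)\n",
              length(x$sets), cats[["oncogenic"]], cats[["ddr"]],
              cats[["other"]]))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.pathway_catalog <- function(x) length(x$sets)

#' Set names of a catalog
#' @param catalog A `pathway_catalog`.
#' @return Character vector of set names, in catalog order.
#' @export
catalog_names <- function(catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  names(catalog$sets)
}

#' Names of the DDR-category sets in a catalog
#' @param catalog A `pathway_catalog`.
#' @return Character vector of set names with category `"ddr"`.
#' @export
ddr_names <- function(catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  nm <- catalog_names(catalog)
  nm[vapply(catalog$sets, function(s) s$category, character(1)) == "ddr"]
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name  description  gene  gene ...`. Gene symbols are uppercased.
#'
#' @param path Path to a GMT file.
#' @param categories Optional named character vector or data frame
#'   (columns `pathway`, `category`) mapping set name to category; sets not
#'   in the map default to `"other"`.
#' @return List of `gene_set` objects.
#' @export
read_gmt <- function(path, categories = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  cat_map <- .category_map(categories)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields, got ", length(fields))
    nm <- fields[[1]]
    category <- if (!is.null(cat_map) && nm %in% names(cat_map))
      cat_map[[nm]] else "other"
    sets[[i]] <- gene_set(nm, fields[-(1:2)], category = category,
                          description = fields[[2]])
  }
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate set name(s) in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  sets
}

.category_map <- function(categories) {
  if (is.null(categories)) return(NULL)
  if (is.data.frame(categories)) {
    stopifnot(all(c("pathway", "category") %in% names(categories)))
    categories <- stats::setNames(as.character(categories$category),
                                  categories$pathway)
  }
  categories <- vapply(categories, as.character, character(1))
  bad <- setdiff(unique(categories), c("oncogenic", "ddr", "other"))
  if (length(bad))
    stop("unknown categories in map: ", paste(bad, collapse = ", "))
  categories
}

#' Read a pathway-to-category sidecar table
#'
#' @param path TSV with header columns `pathway` and `category`.
#' @return Named character vector mapping pathway name to category.
#' @export
read_category_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .category_map(df)
}

#' Write gene sets to a GMT file
#'
#' @param sets List of `gene_set` objects (a `pathway_catalog` is accepted).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "pathway_catalog")) sets <- sets$sets
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write GMT to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' The packaged default 18-pathway catalog
#'
#' Ten canonical oncogenic signaling pathways (cell cycle, Hippo, Myc, Notch,
#' Nrf2, PI3K, RTK/RAS, TGF-beta, p53, Wnt) and the eight DNA damage response
#' pathways (MMR, BER, CPF, FA, HRR, NER, NHEJ, TLS). Gene membership ships
#' as a versioned GMT fixture curated from the public pathway literature; it
#' is configuration, not code — pass your own GMT plus category map to
#' [read_gmt()] to override it.
#'
#' @return A `pathway_catalog` with exactly 10 oncogenic and 8 DDR sets.
#' @export
default_catalog <- function() {
  gmt <- system.file("extdata", "pathways_default.gmt", package = "copath")
  cats <- system.file("extdata", "pathway_categories.tsv", package = "copath")
  if (!nzchar(gmt) || !nzchar(cats))
    stop("packaged default catalog fixture is missing; reinstall the package")
  sets <- read_gmt(gmt, categories = read_category_map(cats))
  catalog <- pathway_catalog(
    sets,
    provenance = "packaged default catalog (curated stand-in gene lists)")
  .validate_default_catalog(catalog)
  catalog
}

.validate_default_catalog <- function(catalog) {
  cats <- vapply(catalog$sets, function(s) s$category, character(1))
  if (sum(cats == "oncogenic") != 10L || sum(cats == "ddr") != 8L)
    stop("default catalog corrupt: expected 10 oncogenic + 8 ddr sets")
  if (!"NOTCH" %in% catalog_names(catalog))
    stop("default catalog corrupt: NOTCH set missing")
  expected_ddr <- c("MMR", "BER", "CPF", "FA", "HRR", "NER", "NHEJ", "TLS")
  if (!setequal(ddr_names(catalog), expected_ddr))
    stop("default catalog corrupt: DDR set names differ from ",
         paste(expected_ddr, collapse = ","))
  invisible(catalog)
}

#' Restrict a catalog to a targeted gene panel
#'
#' Intersects each set with the panel, mirroring the effect of running the
#' pathway analysis on targeted-sequencing data: sets whose intersection is
#' empty are dropped, so co-alteration denominators reflect only assayable
#' pathways.
#'
#' @param catalog A `pathway_catalog`.
#' @param panel Non-empty character vector of assayed gene symbols.
#' @return A `pathway_catalog`; provenance records the panel size and any
#'   dropped sets.
#' @export
restrict_catalog <- function(catalog, panel) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  panel <- toupper(as.character(panel))
  if (length(panel) == 0L) stop("panel must be non-empty")
  kept <- list()
  dropped <- character(0)
  for (s in catalog$sets) {
    genes <- intersect(s$genes, panel)
    if (length(genes)) {
      kept[[length(kept) + 1L]] <- gene_set(s$name, genes,
                                            category = s$category,
                                            description = s$description)
    } else {
      dropped <- c(dropped, s$name)
    }
  }
  prov <- sprintf("%s | restricted to %d-gene panel%s",
                  catalog$provenance, length(unique(panel)),
                  if (length(dropped))
                    paste0("; dropped empty sets: ",
                           paste(dropped, collapse = ","))
                  else "")
  if (length(kept) == 0L)
    prov <- paste(prov, "| WARNING: no set overlaps the panel")
  pathway_catalog(kept, provenance = prov)
}
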