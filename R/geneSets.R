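#' Gene set collection
#'
#' An S4 container for named gene sets (pathways, signatures) as read from
#' GMT files. Set names are unique, every set is nonempty, and gene
#' identifiers are case-normalized (upper case) on construction so that
#' lookups against expression matrices are case-insensitive.
#'
#' @slot sets Named list of character vectors of gene identifiers.
#' @slot descriptions Character vector of per-set descriptions, parallel to
#'   \code{sets}.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- NULL
  nm <- names(object@sets)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    msg <- c(msg, "all gene sets must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, "gene set names must be unique")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must be parallel to sets")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "gene sets must be nonempty")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "gene sets must be character vectors")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors (gene identifiers).
#' @param descriptions Optional character vector of descriptions; defaults
#'   to the set names.
#' @return A \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(ifn = c("STAT1", "IRF7"), bcr = c("LYN", "SYK")))
#' geneSets(gsc)$ifn
#' @export
GeneSetCollection <- function(sets, descriptions = names(sets)) {
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  new("GeneSetCollection", sets = sets,
      descriptions = as.character(descriptions))
}

#' @describeIn GeneSetCollection-accessors the named list of gene sets
#' @export
geneSets <- function(x) x@sets

#' Accessors for GeneSetCollection
#'
#' @param x A \linkS4class{GeneSetCollection}.
#' @name GeneSetCollection-accessors
#' @aliases setDescriptions length,GeneSetCollection-method
NULL

#' @describeIn GeneSetCollection-accessors per-set description strings
#' @export
setDescriptions <- function(x) stats::setNames(x@descriptions, names(x@sets))

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = TRUE) {
  new("GeneSetCollection", sets = x@sets[i],
      descriptions = x@descriptions[if (is.character(i)) match(i, names(x@sets)) else i])
})

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  sz <- lengths(object@sets)
  cat("  set sizes:", min(sz), "-", max(sz), "genes\n")
  shown <- utils::head(names(object@sets), 5)
  cat("  names:", paste(shown, collapse = ", "),
      if (length(object@sets) > 5) "..." else "", "\n")
})

#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set name, description, then one gene per field.
#' Lines with fewer than three fields and duplicated set names are rejected
#' with the offending line number.
#'
#' @param path Path to a GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1], " of '", path,
         "' has fewer than 3 tab-separated fields")
  nms <- vapply(fields, `[[`, character(1), 1L)
  dup <- which(duplicated(nms))
  if (length(dup))
    stop("duplicate gene-set name '", nms[dup[1]], "' at GMT line ", dup[1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  GeneSetCollection(sets, vapply(fields, `[[`, character(1), 2L))
}

#' Write a GMT gene-set file
#'
#' @param x A \linkS4class{GeneSetCollection}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  desc <- setDescriptions(x)
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, desc[[nm]], x[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
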