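# Small shared helpers: argument checks, seed scoping, GMT i/o.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are deterministic without
#' disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a GMT gene-set file
#'
#' @param path path to a tab-separated GMT file (name, description, genes...).
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stopf("malformed GMT line: need name, description, >=1 gene")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stopf("duplicate gene-set names in %s", path)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description single description string recycled per set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "stateatlas") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("all gene sets must be named")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Gene-class prefixes used by QC and marker exclusion rules; configurable at
# the call sites, these are the package-wide defaults.
default_class_regex <- function() {
  c(mito = "^MT-", rpl = "^RPL", hsp = "^HSP")
}
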