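#' Construct a concept hierarchy
#'
#' A concept hierarchy holds coded clinical concepts (SNOMED-style) together
#' with their child-to-parent subsumption relation. The relation may be
#' polyhierarchical (a concept can have several parents) but must be acyclic;
#' a hierarchy containing a directed cycle is rejected at construction time.
#'
#' @param concepts A data frame with columns `code` (non-empty, unique
#'   character identifiers) and `display` (human-readable labels).
#' @param edges A data frame with columns `child_code` and `parent_code`;
#'   every endpoint must be a code present in `concepts`. May have zero rows.
#'
#' @return An object of class `concept_hierarchy`.
#' @examples
#' h <- concept_hierarchy(
#'   concepts = data.frame(code = c("neo", "mal"), display = c("Neoplasm", "Malignant")),
#'   edges = data.frame(child_code = "mal", parent_code = "neo")
#' )
#' descendants(h, "neo")
#' @export
concept_hierarchy <- function(concepts, edges) {
  concepts <- tibble::as_tibble(concepts)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("code", "display") %in% names(concepts)))
  if (nrow(edges) > 0) {
    stopifnot(all(c("child_code", "parent_code") %in% names(edges)))
  } else {
    edges <- tibble::tibble(child_code = character(), parent_code = character())
  }
  concepts$code <- as.character(concepts$code)
  if (any(is.na(concepts$code) | !nzchar(concepts$code))) {
    stop("concept codes must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(concepts$code)) {
    dup <- unique(concepts$code[duplicated(concepts$code)])
    stop("duplicate concept code(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  edges$child_code <- as.character(edges$child_code)
  edges$parent_code <- as.character(edges$parent_code)
  missing <- setdiff(unique(c(edges$child_code, edges$parent_code)), concepts$code)
  if (length(missing) > 0) {
    stop("edge endpoint(s) not defined as concepts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  # children map: parent code -> character vector of direct children
  children <- split(edges$child_code, factor(edges$parent_code, levels = concepts$code))
  children <- lapply(children, unique)

  h <- structure(
    list(concepts = concepts, edges = edges, children = children),
    class = "concept_hierarchy"
  )
  assert_acyclic(h)
  h
}

# Kahn's algorithm on the child->parent relation; a leftover node set means
# a directed cycle.
assert_acyclic <- function(h) {
  codes <- h$concepts$code
  if (nrow(h$edges) == 0) return(invisible(TRUE))
  indeg <- stats::setNames(integer(length(codes)), codes)
  tab <- table(h$edges$child_code)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    kids <- h$children[[node]]
    for (k in kids) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (seen < length(codes)) {
    cyc <- names(indeg)[indeg > 0L]
    stop("concept hierarchy contains a directed cycle involving: ",
         paste(cyc, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.concept_hierarchy <- function(x, ...) {
  cat("<concept_hierarchy> ", nrow(x$concepts), " concepts, ",
      nrow(x$edges), " subsumption edges\n", sep = "")
  invisible(x)
}

has_code <- function(hierarchy, code) code %in% hierarchy$concepts$code

check_code <- function(hierarchy, code) {
  if (!has_code(hierarchy, code)) {
    stop("unknown concept code: '", code, "'", call. = FALSE)
  }
  invisible(code)
}

#' All descendants of a concept
#'
#' Returns every code subsumed under `code` via the child-of relation,
#' excluding `code` itself. A leaf concept has no descendants.
#'
#' @param hierarchy A [concept_hierarchy()].
#' @param code A concept code present in the hierarchy.
#' @return A character vector of descendant codes (possibly empty), sorted.
#' @export
descendants <- function(hierarchy, code) {
  stopifnot(inherits(hierarchy, "concept_hierarchy"))
  check_code(hierarchy, code)
  out <- character(0)
  frontier <- hierarchy$children[[code]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(hierarchy$children[frontier], use.names = FALSE))
  }
  sort(unique(out))
}

#' Define a value-set rule
#'
#' A value-set rule is a list of include terms and exclude terms over a
#' concept hierarchy. Each term is a concept code with a flag saying whether
#' the term covers the concept's descendants as well ("including
#' descendants"). Exclusion always wins over inclusion.
#'
#' @param includes,excludes Either a character vector of codes (all terms get
#'   `with_descendants = TRUE`, the usual SNOMED convention) or a data frame
#'   with columns `code` and `with_descendants`.
#' @return An object of class `value_set_rule`.
#' @export
value_set_rule <- function(includes, excludes = NULL) {
  norm <- function(x) {
    if (is.null(x)) {
      return(tibble::tibble(code = character(), with_descendants = logical()))
    }
    if (is.character(x)) {
      return(tibble::tibble(code = x, with_descendants = TRUE))
    }
    x <- tibble::as_tibble(x)
    stopifnot(all(c("code", "with_descendants") %in% names(x)))
    tibble::tibble(code = as.character(x$code),
                   with_descendants = as.logical(x$with_descendants))
  }
  structure(list(includes = norm(includes), excludes = norm(excludes)),
            class = "value_set_rule")
}

#' @export
print.value_set_rule <- function(x, ...) {
  term <- function(t) paste0(t$code, ifelse(t$with_descendants, " (+desc)", ""))
  cat("<value_set_rule>\n  include: ",
      paste(term(x$includes), collapse = " OR "), "\n", sep = "")
  if (nrow(x$excludes) > 0) {
    cat("  AND NOT: ", paste(term(x$excludes), collapse = " OR "), "\n", sep = "")
  }
  invisible(x)
}

expand_term <- function(hierarchy, code, with_descendants) {
  check_code(hierarchy, code)
  if (with_descendants) c(code, descendants(hierarchy, code)) else code
}

#' Expand a value-set rule against a hierarchy
#'
#' Computes the union of all include-term expansions minus the union of all
#' exclude-term expansions, where a term expansion is the anchor code itself
#' plus (optionally) its descendants. An empty include list yields an empty
#' value set; an unknown code is an error naming the code.
#'
#' @param hierarchy A [concept_hierarchy()].
#' @param rule A [value_set_rule()].
#' @return An object of class `value_set` with elements `codes` (sorted
#'   character vector) and `rule`.
#' @export
expand_value_set <- function(hierarchy, rule) {
  stopifnot(inherits(hierarchy, "concept_hierarchy"),
            inherits(rule, "value_set_rule"))
  inc <- unlist(Map(function(code, wd) expand_term(hierarchy, code, wd),
                    rule$includes$code, rule$includes$with_descendants),
                use.names = FALSE)
  exc <- unlist(Map(function(code, wd) expand_term(hierarchy, code, wd),
                    rule$excludes$code, rule$excludes$with_descendants),
                use.names = FALSE)
  structure(list(codes = sort(unique(setdiff(inc, exc))), rule = rule),
            class = "value_set")
}

#' @export
print.value_set <- function(x, ...) {
  cat("<value_set> ", length(x$codes), " codes\n", sep = "")
  invisible(x)
}

#' Does a Problem List match a value set?
#'
#' @param problems A data frame of Problem-List entries with a `code` column,
#'   or a character vector of codes. Zero entries match nothing.
#' @param value_set A `value_set` from [expand_value_set()].
#' @return `TRUE` iff at least one entry's code is in the value set.
#' @export
problem_list_matches <- function(problems, value_set) {
  stopifnot(inherits(value_set, "value_set"))
  codes <- if (is.data.frame(problems)) problems$code else problems
  any(codes %in% value_set$codes)
}

#' Read a concept hierarchy from CSV files
#'
#' Expects `concepts.csv` (columns `code`, `display`) and `edges.csv`
#' (columns `child_code`, `parent_code`) in `dir`.
#'
#' @param dir Directory containing the two files.
#' @return A [concept_hierarchy()].
#' @export
read_concept_hierarchy <- function(dir) {
  concepts <- readr::read_csv(file.path(dir, "concepts.csv"),
                              col_types = readr::cols(.default = "c"))
  edges <- readr::read_csv(file.path(dir, "edges.csv"),
                           col_types = readr::cols(.default = "c"))
  concept_hierarchy(concepts, edges)
}

#' Write a concept hierarchy to CSV files
#'
#' @param hierarchy A [concept_hierarchy()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_concept_hierarchy <- function(hierarchy, dir) {
  stopifnot(inherits(hierarchy, "concept_hierarchy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(hierarchy$concepts, file.path(dir, "concepts.csv"))
  readr::write_csv(hierarchy$edges, file.path(dir, "edges.csv"))
  invisible(dir)
}

#' Read a value-set rule from YAML
#'
#' The YAML document carries `includes` and (optionally) `excludes`, each a
#' list of `{code, with_descendants}` mappings.
#'
#' @param path Path to the YAML file.
#' @return A [value_set_rule()].
#' @export
read_value_set_rule <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(terms) {
    if (is.null(terms) || length(terms) == 0) return(NULL)
    tibble::tibble(
      code = vapply(terms, function(t) as.character(t$code), character(1)),
      with_descendants = vapply(terms, function(t) {
        isTRUE(t$with_descendants) || is.null(t$with_descendants)
      }, logical(1))
    )
  }
  value_set_rule(includes = to_df(y$includes), excludes = to_df(y$excludes))
}
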