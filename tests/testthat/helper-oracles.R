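# Independent oracles and fixture builders shared across tests.

# Random DAG: edges always point from a higher-indexed child to a
# lower-indexed parent, so acyclicity holds by construction.
random_dag <- function(n_nodes, p_edge = 0.08, seed = 1) {
  set.seed(seed)
  codes <- sprintf("N%03d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  list(
    concepts = tibble::tibble(code = codes, display = codes),
    edges = tibble::tibble(child_code = codes[pairs[keep, 2]],
                           parent_code = codes[pairs[keep, 1]])
  )
}

# Brute-force reflexive-free transitive closure by repeated boolean matrix
# squaring: closure[a, b] is TRUE iff b is reachable below a.
closure_matrix <- function(concepts, edges) {
  codes <- concepts$code
  n <- length(codes)
  A <- matrix(FALSE, n, n, dimnames = list(codes, codes))
  if (nrow(edges) > 0) {
    A[cbind(match(edges$parent_code, codes), match(edges$child_code, codes))] <- TRUE
  }
  R <- A
  repeat {
    R_next <- R | ((R %*% R) > 0)
    if (identical(R_next, R)) break
    R <- R_next
  }
  R
}

oracle_descendants <- function(closure, code) {
  sort(colnames(closure)[closure[code, ]])
}

# Set arithmetic over the closure oracle, mirroring the include/exclude
# semantics independently of the package implementation.
oracle_expand <- function(closure, rule) {
  term <- function(code, wd) if (wd) c(code, oracle_descendants(closure, code)) else code
  inc <- unlist(Map(term, rule$includes$code, rule$includes$with_descendants))
  exc <- unlist(Map(term, rule$excludes$code, rule$excludes$with_descendants))
  sort(unique(setdiff(inc, exc)))
}

# Two-level toy hierarchy used throughout: neoplasm -> {malignant, benign},
# malignant -> breast-ca.
toy_hierarchy <- function() {
  concept_hierarchy(
    concepts = tibble::tibble(
      code = c("neoplasm", "malignant", "benign", "breast-ca"),
      display = c("Neoplasm", "Malignant neoplasm", "Benign neoplasm",
                  "Breast cancer")
    ),
    edges = tibble::tibble(
      child_code = c("malignant", "benign", "breast-ca"),
      parent_code = c("neoplasm", "neoplasm", "malignant")
    )
  )
}

expect_within_3se <- function(k, n, p, label = NULL) {
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(k / n - p), 3 * se + 1e-12, label = label)
}

small_sim <- function(n = 500, seed = 7, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}
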