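#' Guideline-directed medical therapy (GDMT) drug vocabulary
#'
#' Loads the vocabulary used by [classify_gdmt()]: the evidence-based
#' beta-blocker ingredients for reduced-EF cardiomyopathy (carvedilol,
#' metoprolol succinate, bisoprolol), the pharmaceutical class / subclass
#' title phrases that identify ACE inhibitors, angiotensin receptor blockers
#' (ARBs) and mineralocorticoid receptor antagonists (MRAs), and the named
#' ACE-inhibitor combination products whose class titles do not carry the
#' "ACE Inhibitor" phrase. Class and subclass titles mimic drug-database
#' (FDB-style) pharmaceutical class titles; the shipped lists are synthetic
#' stand-ins with realistic cardinalities (2 classes + 7 subclasses for ACE
#' inhibitors, 6 ARB classes, 2 MRA subclasses, 8 combination products), not
#' licensed vendor content.
#'
#' @param dir Directory holding the vocabulary files. Defaults to the copies
#'   installed with the package (`inst/extdata/gdmt`).
#' @return A list of class `gdmt_vocabulary` with elements
#'   `beta_blocker_ingredients`, `acei_phrases`, `acei_class_titles`,
#'   `acei_combinations`, `arb_phrases`, `arb_class_titles`, `mra_phrases`,
#'   `mra_subclass_titles`.
#' @export
gdmt_vocabulary <- function(dir = system.file("extdata", "gdmt", package = "cardioreg")) {
  read_lines_clean <- function(file) {
    x <- readLines(file.path(dir, file), warn = FALSE)
    x <- trimws(x)
    x[nzchar(x) & !startsWith(x, "#")]
  }
  acei <- readr::read_csv(file.path(dir, "acei_classes.csv"),
                          col_types = readr::cols(.default = "c"))
  arb <- readr::read_csv(file.path(dir, "arb_classes.csv"),
                         col_types = readr::cols(.default = "c"))
  mra <- readr::read_csv(file.path(dir, "mra_subclasses.csv"),
                         col_types = readr::cols(.default = "c"))
  structure(list(
    beta_blocker_ingredients = read_lines_clean("gdmt_betablockers.txt"),
    # matching is by phrase containment; the title tables document the
    # concrete classes those phrases are expected to hit
    acei_phrases = "ACE Inhibitor",
    acei_class_titles = acei,
    acei_combinations = read_lines_clean("acei_combinations.txt"),
    arb_phrases = c("Angiotensin Receptor Antagonist",
                    "Angiotensin Receptor Blocker",
                    "Angiotensin II Receptor Blocker",
                    "Angiotensin II Receptor Antagonist"),
    arb_class_titles = arb,
    mra_phrases = "Aldosterone Receptor Antagonist",
    mra_subclass_titles = mra
  ), class = "gdmt_vocabulary")
}

#' @export
print.gdmt_vocabulary <- function(x, ...) {
  cat("<gdmt_vocabulary>\n",
      "  beta-blocker ingredients: ", paste(x$beta_blocker_ingredients, collapse = ", "), "\n",
      "  ACEi combination products: ", length(x$acei_combinations), "\n",
      "  ARB title phrases: ", length(x$arb_phrases), " (+ 'ARB' token)\n", sep = "")
  invisible(x)
}
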