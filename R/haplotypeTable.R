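# Haplotype classification: mapping five-site RFLP profiles to
# classical beta-globin haplotypes or atypical categories, and
# tabulating per-chromosome frequencies and per-individual combinations.

#' Read a haplotype table from JSON
#'
#' @param path Path to a JSON file with fields `version`, `loci`,
#'   `classical` and optionally `atypical`.
#' @return A [HaplotypeTable].
#' @export
readHaplotypeTable <- function(path) {
  raw <- jsonlite::fromJSON(path)
  new("HaplotypeTable",
      loci = as.character(raw$loci),
      classical = unlist(raw$classical),
      atypical = if (is.null(raw$atypical)) c(a = "x")[0] else unlist(raw$atypical),
      version = raw$version)
}

#' The packaged default haplotype table
#'
#' Five classical patterns (Benin, Bantu/CAR, Senegal, Cameroon,
#' Arab-Indian) and five named atypical subtype patterns, version
#' `table-ref16-default`.
#'
#' @return A [HaplotypeTable].
#' @export
#' @examples
#' defaultHaplotypeTable()
defaultHaplotypeTable <- function() {
  readHaplotypeTable(system.file("extdata",
                                 "haplotype_table_ref16_default.json",
                                 package = "sickleHaps"))
}

.is_atypical_label <- function(label)
  grepl("^atypical", label) & label != "unresolved"

#' Classify a five-site RFLP profile
#'
#' Exact match to a classical pattern yields that label; exact match to
#' a named atypical subtype yields the subtype; any other complete
#' profile is `"atypical-other"` (a recombinant of the defining sites);
#' a profile with any missing state is `"unresolved"`.
#'
#' @param profile Character vector of five states over `"+"`, `"-"`,
#'   `NA`, in [RFLP_LOCI] order.
#' @param table A [HaplotypeTable].
#' @return A list with elements `label` and `profile` (as observed).
#' @export
#' @examples
#' tab <- defaultHaplotypeTable()
#' classifyProfile(patternFor(tab, "Benin"), tab)$label
classifyProfile <- function(profile, table = defaultHaplotypeTable()) {
  if (length(profile) != 5L)
    stop("profile must have exactly five states")
  if (!all(profile %in% c("+", "-") | is.na(profile)))
    stop("profile states must be '+', '-' or NA")
  if (anyNA(profile))
    return(list(label = "unresolved", profile = profile))
  pat <- paste(profile, collapse = "")
  label <- if (pat %in% table@classical)
    names(table@classical)[match(pat, table@classical)]
  else if (length(table@atypical) && pat %in% table@atypical)
    names(table@atypical)[match(pat, table@atypical)]
  else "atypical-other"
  list(label = label, profile = profile)
}

#' Classify every chromosome of a profile table
#'
#' @param profiles A `data.frame` holding the five [RFLP_LOCI] state
#'   columns (e.g. [chromosomes()] of a [Cohort], or the output of
#'   [digestCohort()]).
#' @inheritParams classifyProfile
#' @return Character vector of haplotype labels, one per row.
#' @export
classifyProfiles <- function(profiles, table = defaultHaplotypeTable()) {
  miss <- setdiff(RFLP_LOCI, names(profiles))
  if (length(miss))
    stop("profile table lacks locus columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(profiles[RFLP_LOCI])
  vapply(seq_len(nrow(m)), function(i)
    classifyProfile(unname(m[i, ]), table)$label, character(1))
}

#' Per-chromosome haplotype frequencies
#'
#' Tabulates resolved haplotype calls as counts and proportions of the
#' resolved-chromosome denominator, the way cohort haplotype tables
#' report "number of chromosomes presenting with a specific haplotype".
#' Unresolved calls are excluded from the denominator and reported
#' separately.
#'
#' @param calls Character vector of labels from [classifyProfiles()].
#' @param grouping `"fine"` keeps atypical subtypes distinct;
#'   `"classical-vs-atypical"` collapses every atypical label
#'   (subtypes and `"atypical-other"`) into `"atypical"`.
#' @param population Optional population label carried into the result.
#' @return A list with `table` (`data.frame` of `category`, `count`,
#'   `proportion`, `percent`), `denominator` (resolved chromosomes),
#'   `nUnresolved` and `population`.
#' @export
#' @examples
#' haplotypeFrequencies(c("Benin", "Benin", "atypical-I", "atypical-other"),
#'                      grouping = "classical-vs-atypical")
haplotypeFrequencies <- function(calls,
                                 grouping = c("fine", "classical-vs-atypical"),
                                 population = NA_character_) {
  grouping <- match.arg(grouping)
  resolved <- calls[calls != "unresolved"]
  if (!length(resolved))
    stop("no resolved haplotype calls to tabulate")
  if (grouping == "classical-vs-atypical")
    resolved[.is_atypical_label(resolved)] <- "atypical"
  counts <- table(resolved)
  denom <- length(resolved)
  tab <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    proportion = as.numeric(counts) / denom,
                    stringsAsFactors = FALSE)
  tab$percent <- round(100 * tab$proportion, 1)
  tab <- tab[order(-tab$count, tab$category), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, denominator = denom,
       nUnresolved = sum(calls == "unresolved"), population = population)
}

#' Per-individual haplotype-pair combinations
#'
#' Pairs the two chromosome-level calls of each individual into an
#' unordered combination label ("the pair of haplotypes inherited in
#' two separate chromosomes"). Atypical subtypes are collapsed to
#' `"atypical"` by default, matching the granularity at which cohort
#' combination tables are reported. Individuals with an unresolved
#' chromosome are excluded from the denominator.
#'
#' @param individuals Character vector of individual ids, one per call.
#' @param calls Haplotype labels, aligned with `individuals`; each id
#'   must appear exactly twice.
#' @param collapseAtypical Collapse atypical subtypes before pairing
#'   (default `TRUE`).
#' @return A list with `records` (`data.frame` of `individual`,
#'   `combination`), `table` (counts/proportions over fully resolved
#'   individuals), `denominator` and `nUnresolved`.
#' @export
#' @examples
#' pairCombinations(rep(c("i1", "i2"), each = 2),
#'                  c("Benin", "atypical-I", "Benin", "Benin"))
pairCombinations <- function(individuals, calls, collapseAtypical = TRUE) {
  stopifnot(length(individuals) == length(calls))
  tally <- table(individuals)
  bad <- names(tally)[tally != 2L]
  if (length(bad))
    stop("individuals without exactly two calls: ",
         paste(bad, collapse = ", "))
  if (collapseAtypical)
    calls[.is_atypical_label(calls)] <- "atypical"
  ids <- unique(individuals)
  combo <- vapply(ids, function(id) {
    pair <- calls[individuals == id]
    if (any(pair == "unresolved")) return(NA_character_)
    paste(sort(pair), collapse = "/")
  }, character(1))
  records <- data.frame(individual = ids, combination = combo,
                        stringsAsFactors = FALSE)
  ok <- !is.na(combo)
  if (!any(ok)) stop("no individuals with both chromosomes resolved")
  counts <- table(combo[ok])
  denom <- sum(ok)
  tab <- data.frame(combination = names(counts),
                    count = as.integer(counts),
                    proportion = as.numeric(counts) / denom,
                    stringsAsFactors = FALSE)
  tab$percent <- round(100 * tab$proportion, 1)
  tab <- tab[order(-tab$count, tab$combination), , drop = FALSE]
  rownames(tab) <- NULL
  list(records = records, table = tab, denominator = denom,
       nUnresolved = sum(!ok))
}
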