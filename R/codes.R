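# Diagnosis code sets and code matching.
#
# Claims diagnoses are ICD-9-CM: a 3-digit rubric, optionally followed by a
# dot and further digits ("042", "054.3", "003.21"). A code set is a list of
# patterns, each either a prefix at any depth or an inclusive range of
# 3-digit rubrics written "lo-hi". Matching is prefix-based at the rubric
# level, the convention of Taiwanese claims studies: a listed 3-digit code
# includes all of its sub-rubrics.

.pattern_ok <- function(p) {
  grepl("^[0-9]{3}(\\.[0-9]+)?$", p) | grepl("^[0-9]{3}-[0-9]{3}$", p)
}

#' Construct a diagnosis code set
#'
#' @param name label for the set (used in messages and outputs).
#' @param entries character vector of patterns: a bare 3-digit rubric
#'   (`"013"`, matches all of 013.x), a dotted prefix (`"054.3"`, matches
#'   054.3 and 054.30, 054.31, ...), or an inclusive rubric range
#'   (`"042-044"`).
#' @return an object of class `code_set`.
#' @export
#' @examples
#' hiv <- code_set("hiv", "042-044")
#' match_code("043.1", hiv)
code_set <- function(name, entries) {
  entries <- as.character(entries)
  if (length(entries) == 0 || any(!nzchar(entries)))
    stop_config("code set `%s` has empty entries", name)
  bad <- entries[!.pattern_ok(entries)]
  if (length(bad) > 0)
    stop_config("code set `%s`: malformed pattern(s): %s",
                name, paste(bad, collapse = ", "))
  rng <- grepl("-", entries, fixed = TRUE)
  lo <- hi <- rep(NA_integer_, length(entries))
  lo[rng] <- as.integer(substr(entries[rng], 1, 3))
  hi[rng] <- as.integer(substr(entries[rng], 5, 7))
  if (any(lo[rng] > hi[rng]))
    stop_config("code set `%s`: range low > high", name)
  structure(list(name = name, entries = entries,
                 is_range = rng, lo = lo, hi = hi),
            class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set> ", x$name, ": ", paste(x$entries, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Test diagnosis codes against a code set
#'
#' A code matches when it equals a pattern, extends a dotted pattern
#' (`"054.30"` matches `"054.3"`), extends a bare 3-digit rubric
#' (`"013.1"` matches `"013"`), or its rubric falls inside a listed range.
#'
#' @param code character vector of ICD-9-CM codes.
#' @param cs a [code_set()].
#' @return logical vector, one element per code.
#' @export
match_code <- function(code, cs) {
  stopifnot(inherits(cs, "code_set"))
  code <- as.character(code)
  if (any(!nzchar(code) | is.na(code)))
    stop_data("empty diagnosis code")
  bad <- !grepl("^[0-9]{3}(\\.[0-9]*)?$", code)
  if (any(bad))
    stop_data("malformed diagnosis code(s): %s",
              paste(unique(code[bad]), collapse = ", "))
  rubric <- as.integer(substr(code, 1, 3))
  out <- rep(FALSE, length(code))
  for (j in seq_along(cs$entries)) {
    if (cs$is_range[j]) {
      out <- out | (rubric >= cs$lo[j] & rubric <= cs$hi[j])
    } else {
      p <- cs$entries[j]
      if (grepl(".", p, fixed = TRUE)) {
        out <- out | code == p | startsWith(code, p)
      } else {
        out <- out | substr(code, 1, 3) == p
      }
    }
  }
  out
}

#' Load the shipped diagnosis code sets
#'
#' Reads the YAML files under `inst/extdata/codes/`: the HIV/AIDS case set
#' (042-044), the four neurological-disease subtype sets (CNS infections,
#' cognitive disorders, vasculopathy, peripheral neuropathy), the
#' malignancy exclusion set, and the six opportunistic-infection flag sets.
#' Users can point `dir` at an edited copy to change any list.
#'
#' @param dir directory of YAML code files (default: the shipped copies).
#' @return named list of [code_set()] objects; the opportunistic-infection
#'   sets are nested under `$opportunistic`.
#' @export
default_code_sets <- function(dir = system.file("extdata", "codes",
                                                package = "herbsurv")) {
  read_one <- function(file) {
    y <- yaml::read_yaml(file.path(dir, file))
    lapply(names(y), function(nm) code_set(nm, unlist(y[[nm]]))) |>
      setNames(names(y))
  }
  core <- read_one("case_definitions.yaml")
  oi <- read_one("opportunistic_infections.yaml")
  c(core, list(opportunistic = oi))
}

# Quan's ICD-9-CM Charlson mapping, shipped as CSV (category, weight,
# pattern). Cached per session.
.charlson_env <- new.env(parent = emptyenv())

#' Load the Charlson comorbidity mapping
#'
#' Quan's ICD-9-CM enhanced Charlson table as shipped under
#' `inst/extdata/charlson_quan_icd9.csv`. Status V-codes are omitted
#' (the matching grammar is numeric); see the methods vignette.
#'
#' @return tibble with columns `category`, `weight`, `pattern`.
#' @export
charlson_map <- function() {
  if (is.null(.charlson_env$map)) {
    f <- system.file("extdata", "charlson_quan_icd9.csv",
                     package = "herbsurv")
    .charlson_env$map <- tibble::as_tibble(
      read.csv(f, colClasses = c("character", "integer", "character")))
  }
  .charlson_env$map
}

#' Categorise a cause-of-death code
#'
#' Maps a death-certificate code to one of eight cause categories
#' (infections and parasites; circulatory; endocrine, nutritional and
#' metabolic; viral hepatitis and liver; respiratory; genitourinary;
#' neoplasms; other) using chapter-level ranges. Hepatitis/liver is tested
#' first because its codes sit inside the infectious-disease chapter.
#'
#' @param cause_code character vector of ICD-9-CM or ICD-10-CM codes.
#' @param icd_version integer vector (9 or 10), recycled.
#' @return character vector of category labels; unparseable codes map to
#'   `"other"` with a warning.
#' @export
#' @examples
#' categorize_cause("A41.9", 10) # infections_parasites
#' categorize_cause("I21.0", 10) # circulatory
categorize_cause <- function(cause_code, icd_version = 9) {
  code <- as.character(cause_code)
  ver <- rep_len(as.integer(icd_version), length(code))
  out <- character(length(code))
  for (i in seq_along(code)) {
    out[i] <- if (ver[i] == 9) .cause9(code[i]) else .cause10(code[i])
  }
  out
}

.cause9 <- function(code) {
  if (is.na(code) || !grepl("^[0-9]{3}", code)) {
    warning(sprintf("unparseable ICD-9 cause code '%s'; categorised as other",
                    code))
    return("other")
  }
  r <- as.integer(substr(code, 1, 3))
  if (r == 70 || (r >= 571 && r <= 573)) return("hepatitis_liver")
  if (r >= 1 && r <= 139) return("infections_parasites")
  if (r >= 390 && r <= 459) return("circulatory")
  if (r >= 240 && r <= 279) return("endocrine_metabolic")
  if (r >= 460 && r <= 519) return("respiratory")
  if (r >= 580 && r <= 629) return("genitourinary")
  if (r >= 140 && r <= 239) return("neoplasms")
  "other"
}

.cause10 <- function(code) {
  if (is.na(code) || !grepl("^[A-Za-z][0-9]{2}", code)) {
    warning(sprintf("unparseable ICD-10 cause code '%s'; categorised as other",
                    code))
    return("other")
  }
  ch <- toupper(substr(code, 1, 1))
  num <- as.integer(substr(code, 2, 3))
  if ((ch == "B" && num >= 15 && num <= 19) ||
      (ch == "K" && num >= 70 && num <= 77)) return("hepatitis_liver")
  if (ch == "A" || ch == "B") return("infections_parasites")
  if (ch == "I") return("circulatory")
  if (ch == "E" && num <= 90) return("endocrine_metabolic")
  if (ch == "J") return("respiratory")
  if (ch == "N") return("genitourinary")
  if (ch == "C" || (ch == "D" && num <= 48)) return("neoplasms")
  "other"
}
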