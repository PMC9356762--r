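## ICD-10 cause-of-death grouping.
##
## Codes are classified at 3-character block resolution except where a rule
## is stated at 4-character resolution (R09.2, U07.1): a 4-character input is
## checked against 4-character rules first, then falls back to its block.

.pkg_cache <- new.env(parent = emptyenv())

#' Normalize ICD-10 codes
#'
#' Accepts common spellings ("J129", "j12.9", "U7.1") and returns the
#' canonical form: an uppercase letter, a two-digit block (zero-padded), and
#' an optional "." plus 1-2 further digits. Normalization is idempotent and
#' case-insensitive; `"J129"` and `"J12.9"` share the block `"J12"`.
#'
#' @param x character vector of raw codes.
#' @return data.frame with columns `raw`, `normalized`, `block` (letter +
#'   two digits), `sub` (subcode digits, `""` if none).
#' @examples
#' normalizeIcd10(c("J129", "u7.1", "R54"))
#' @export
normalizeIcd10 <- function(x) {
  raw <- as.character(x)
  s <- toupper(trimws(raw))
  m <- regmatches(s, regexec("^([A-Z])([0-9]{1,2})(?:\\.([0-9]{1,2}))?$", s))
  nodot <- regmatches(s, regexec("^([A-Z])([0-9]{3,4})$", s))
  letter <- block <- sub <- character(length(s))
  for (i in seq_along(s)) {
    if (length(m[[i]])) {
      letter[i] <- m[[i]][2]
      block[i] <- sprintf("%02d", as.integer(m[[i]][3]))
      sub[i] <- m[[i]][4]
    } else if (length(nodot[[i]])) {
      d <- nodot[[i]][3]
      letter[i] <- nodot[[i]][2]
      block[i] <- substr(d, 1, 2)
      sub[i] <- substr(d, 3, nchar(d))
    } else {
      stop("malformed ICD-10 code: ", dQuote(raw[i]), call. = FALSE)
    }
  }
  data.frame(
    raw = raw,
    normalized = paste0(letter, block, ifelse(sub == "", "", paste0(".", sub))),
    block = paste0(letter, block),
    sub = sub,
    stringsAsFactors = FALSE
  )
}

#' Read a cause-mapping table
#'
#' The mapping ships as a plain-text table (category, range_start, range_end)
#' so it can be audited or edited without code changes. Range endpoints are
#' inclusive; a range whose start carries a subcode (e.g. `R09.2`) applies at
#' 4-character resolution.
#'
#' @param path path to a tab-delimited mapping file; default is the table
#'   shipped with the package.
#' @return data.frame with columns category, range_start, range_end plus
#'   parsed helper columns.
#' @export
readCauseMap <- function(path = system.file("extdata", "icd10_cause_map.tsv",
                                            package = "exmort")) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("category", "range_start", "range_end") %in% names(map)))
  lo <- normalizeIcd10(map$range_start)
  hi <- normalizeIcd10(map$range_end)
  map$letter <- substr(lo$block, 1, 1)
  stopifnot(all(map$letter == substr(hi$block, 1, 1)))
  map$lo_num <- as.integer(substr(lo$block, 2, 3))
  map$hi_num <- as.integer(substr(hi$block, 2, 3))
  map$sub <- lo$sub  # "" = block-resolution rule
  map
}

.causeMap <- function() {
  if (is.null(.pkg_cache$causeMap)) .pkg_cache$causeMap <- readCauseMap()
  .pkg_cache$causeMap
}

#' Classify ICD-10 underlying-cause codes into analysis categories
#'
#' Maps each code to exactly one of `RESPIRATORY`, `CIRCULATORY`,
#' `MALIGNANT_NEOPLASM`, `SENILITY`, `COVID19`, or `OTHER`. 4-character
#' rules (R09.2 respiratory; U07.1 COVID-19, also accepted as "U7.1") take
#' precedence over block ranges. U04 (SARS) is respiratory; U07.2 is not
#' treated as COVID-19 because only the laboratory-confirmed code is
#' excluded from the non-COVID aggregate.
#'
#' @param code character vector of ICD-10 codes.
#' @param map mapping table from [readCauseMap()].
#' @return character vector of categories (same length as `code`).
#' @examples
#' classifyCause(c("J12.9", "R54", "U07.1", "A09", "I50"))
#' @export
classifyCause <- function(code, map = .causeMap()) {
  nc <- normalizeIcd10(code)
  out <- rep("OTHER", nrow(nc))
  sub1 <- substr(nc$sub, 1, 1)  # 4-char resolution: block + first subdigit
  rules4 <- map[map$sub != "", ]
  rules3 <- map[map$sub == "", ]
  done <- rep(FALSE, nrow(nc))
  for (j in seq_len(nrow(rules4))) {
    hit <- !done & nc$block == paste0(rules4$letter[j],
                                      sprintf("%02d", rules4$lo_num[j])) &
      sub1 == rules4$sub[j]
    out[hit] <- rules4$category[j]
    done <- done | hit
  }
  letter <- substr(nc$block, 1, 1)
  num <- as.integer(substr(nc$block, 2, 3))
  for (j in seq_len(nrow(rules3))) {
    hit <- !done & letter == rules3$letter[j] &
      num >= rules3$lo_num[j] & num <= rules3$hi_num[j]
    out[hit] <- rules3$category[j]
    done <- done | hit
  }
  out
}

#' Is a death non-COVID-19?
#'
#' `TRUE` for every well-formed code whose category is not `COVID19`; used
#' to build the non-COVID all-cause stratum.
#'
#' @inheritParams classifyCause
#' @return logical vector.
#' @examples
#' nonCovidAllCause(c("C50", "U07.1", "R09.2"))
#' @export
nonCovidAllCause <- function(code, map = .causeMap()) {
  classifyCause(code, map) != "COVID19"
}
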