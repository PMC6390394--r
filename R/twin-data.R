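# Five-group twin dataset container and CSV I/O.

ZYG_LEVELS <- c("MZm", "DZm", "MZf", "DZf", "DOS")

twinkit_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "twinkit_error")))
}

validation_error <- function(msg) twinkit_error(msg, "twinkit_validation_error")

#' Construct a validated five-group twin dataset
#'
#' A `twin_dataset` is a wide data frame with one row per twin pair and
#' columns `family_id`, `zyg` (one of `MZm`, `DZm`, `MZf`, `DZf`, `DOS`),
#' `sex1`, `sex2` (`"M"`/`"F"`), `age` (shared by the pair, years) and two
#' columns `<trait>_1`, `<trait>_2` per trait. Individual trait cells may be
#' `NA`; pairs are never dropped here (missingness is handled downstream by
#' full-information maximum likelihood).
#'
#' Validation enforces consistency of `zyg` with the recorded sexes: same-sex
#' groups must have `sex1 == sex2` of the matching sex, and `DOS` pairs must
#' be opposite-sex. For `DOS` pairs twin 1 is the male by convention; pairs
#' supplied female-first are silently reordered (trait columns swapped) so
#' that cross-sex parameters have a stable meaning.
#'
#' @param x data frame with the columns described above.
#' @param traits character vector of trait names; if `NULL`, inferred from
#'   paired `<name>_1`/`<name>_2` columns.
#' @param age_range optional length-2 numeric; ages outside it are an error.
#' @return An object of class `twin_dataset` (a data frame with a `traits`
#'   attribute).
#' @examples
#' df <- data.frame(family_id = c("f1", "f2"), zyg = c("MZm", "DOS"),
#'                  sex1 = c("M", "M"), sex2 = c("M", "F"), age = c(17, 21),
#'                  TE_1 = c(0.4, 0.5), TE_2 = c(0.42, 0.31))
#' d <- twin_dataset(df)
#' group_counts(d)
#' @seealso [read_twin_csv()], [simulate_twins()]
#' @export
twin_dataset <- function(x, traits = NULL, age_range = NULL) {
  if (!is.data.frame(x)) validation_error("`x` must be a data frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("family_id", "zyg", "sex1", "sex2", "age")
  miss <- setdiff(required, names(x))
  if (length(miss))
    validation_error(paste0("missing required columns: ",
                            paste(miss, collapse = ", ")))
  if (is.null(traits)) {
    cand <- sub("_1$", "", grep("_1$", names(x), value = TRUE))
    traits <- cand[paste0(cand, "_2") %in% names(x)]
  }
  if (!length(traits)) validation_error("no trait columns found")
  tcols <- c(rbind(paste0(traits, "_1"), paste0(traits, "_2")))
  miss <- setdiff(tcols, names(x))
  if (length(miss))
    validation_error(paste0("missing trait columns: ",
                            paste(miss, collapse = ", ")))

  x$family_id <- as.character(x$family_id)
  x$zyg <- as.character(x$zyg)
  bad <- which(!x$zyg %in% ZYG_LEVELS)
  if (length(bad))
    validation_error(sprintf(
      "malformed zygosity label %s in row %d (family %s)",
      dQuote(x$zyg[bad[1]]), bad[1], x$family_id[bad[1]]))
  x$sex1 <- as.character(x$sex1)
  x$sex2 <- as.character(x$sex2)
  bad <- which(!(x$sex1 %in% c("M", "F") & x$sex2 %in% c("M", "F")))
  if (length(bad))
    validation_error(sprintf("invalid sex code in row %d (family %s)",
                             bad[1], x$family_id[bad[1]]))

  expected <- list(MZm = c("M", "M"), DZm = c("M", "M"),
                   MZf = c("F", "F"), DZf = c("F", "F"))
  for (g in names(expected)) {
    rows <- which(x$zyg == g)
    bad <- rows[x$sex1[rows] != expected[[g]][1] |
                x$sex2[rows] != expected[[g]][2]]
    if (length(bad))
      validation_error(sprintf(
        "zygosity %s inconsistent with sexes (%s, %s) for family %s",
        g, x$sex1[bad[1]], x$sex2[bad[1]], x$family_id[bad[1]]))
  }
  dos <- which(x$zyg == "DOS")
  bad <- dos[x$sex1[dos] == x$sex2[dos]]
  if (length(bad))
    validation_error(sprintf(
      "DOS pair with same-sex twins (%s, %s) for family %s",
      x$sex1[bad[1]], x$sex2[bad[1]], x$family_id[bad[1]]))
  # male-first convention for opposite-sex pairs
  swap <- dos[x$sex1[dos] == "F"]
  if (length(swap)) {
    for (tr in traits) {
      tmp <- x[swap, paste0(tr, "_1")]
      x[swap, paste0(tr, "_1")] <- x[swap, paste0(tr, "_2")]
      x[swap, paste0(tr, "_2")] <- tmp
    }
    x$sex1[swap] <- "M"
    x$sex2[swap] <- "F"
  }

  x$age <- as.numeric(x$age)
  if (anyNA(x$age)) validation_error("missing or non-numeric age")
  if (!is.null(age_range)) {
    bad <- which(x$age < age_range[1] | x$age > age_range[2])
    if (length(bad))
      validation_error(sprintf("age %.1f outside declared range for family %s",
                               x$age[bad[1]], x$family_id[bad[1]]))
  }
  for (cc in tcols) {
    x[[cc]] <- as.numeric(x[[cc]])
  }
  rownames(x) <- NULL
  structure(x[, c(required, tcols)],
            traits = traits,
            class = c("twin_dataset", "data.frame"))
}

#' @export
print.twin_dataset <- function(x, ...) {
  cat(sprintf("twin_dataset: %d pairs, traits: %s\n",
              nrow(x), paste(traits(x), collapse = ", ")))
  print(group_counts(x))
  invisible(x)
}

#' Trait names of a twin dataset
#' @param data a `twin_dataset`.
#' @return Character vector of trait names.
#' @export
traits <- function(data) attr(data, "traits")

#' Read a five-group twin dataset from CSV
#'
#' Expects one row per twin pair with a header; missing trait cells are
#' encoded as empty strings. The file is validated by [twin_dataset()];
#' malformed zygosity labels or sex/zygosity inconsistencies are errors that
#' name the offending family.
#'
#' @param path CSV file path.
#' @param traits optional character vector naming the trait columns.
#' @inheritParams twin_dataset
#' @return A `twin_dataset`.
#' @export
read_twin_csv <- function(path, traits = NULL, age_range = NULL) {
  if (!file.exists(path))
    twinkit_error(paste0("file not found: ", path), "twinkit_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  twin_dataset(df, traits = traits, age_range = age_range)
}

#' Write a twin dataset to CSV
#'
#' Inverse of [read_twin_csv()]: missing cells are written as empty strings,
#' so `read_twin_csv(write_twin_csv(d, f))` reproduces `d` up to numeric
#' printing precision.
#'
#' @param data a `twin_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_twin_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pair counts per zygosity group
#'
#' @param data a `twin_dataset`.
#' @return Named integer vector over the five groups (zero for absent
#'   groups); the counts sum to `nrow(data)`.
#' @export
group_counts <- function(data) {
  tab <- table(factor(data$zyg, levels = ZYG_LEVELS))
  stats::setNames(as.integer(tab), ZYG_LEVELS)
}

#' Cross-twin coefficients implied by zygosity
#'
#' Classical twin-design weights on the cross-twin covariance of each
#' biometric component: additive genetic effects correlate 1 in MZ pairs and
#' 0.5 in DZ pairs, non-additive (dominance) effects 1 and 0.25, the shared
#' environment 1 in both, and individual-specific effects 0. Opposite-sex
#' pairs default to the DZ values; a freely estimated opposite-sex genetic
#' correlation can override the genetic weight in model fitting.
#'
#' @param group one of `"MZm"`, `"DZm"`, `"MZf"`, `"DZf"`, `"DOS"`.
#' @return Named numeric vector `c(A=, D=, C=)`.
#' @export
zygosity_coefficients <- function(group) {
  group <- match.arg(group, ZYG_LEVELS)
  if (group %in% c("MZm", "MZf")) c(A = 1, D = 1, C = 1)
  else c(A = 0.5, D = 0.25, C = 1)
}
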