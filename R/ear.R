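#' Estimated average requirement (EAR) cut-points for vitamin A
#'
#' Age-bracket EAR cut-offs in micrograms of retinol activity equivalents
#' (ug RAE) per day used by the cut-point method: a child's usual intake is
#' classed inadequate when it falls below the EAR for the child's age/sex
#' bracket. Defaults follow IOM-style values (210 ug RAE/day for ages 12-47
#' months, 275 for 48-59 months) with a configurable infant value for ages
#' 6-11 months defaulting to 190. Values are identical for both sexes but the
#' table carries a sex column so sex-specific cut-offs can be supplied.
#'
#' @param ear_6_11 EAR for ages 6-11 months (ug RAE/day).
#' @param ear_12_47 EAR for ages 12-47 months.
#' @param ear_48_59 EAR for ages 48-59 months.
#' @return A tibble with columns `age_min`, `age_max` (months, inclusive),
#'   `sex` (`"any"` matches every child) and `ear`.
#' @export
default_ear_table <- function(ear_6_11 = 190, ear_12_47 = 210, ear_48_59 = 275) {
  stopifnot(ear_6_11 > 0, ear_12_47 > 0, ear_48_59 > 0)
  tibble::tibble(
    age_min = c(6L, 12L, 48L),
    age_max = c(11L, 47L, 59L),
    sex = "any",
    ear = c(ear_6_11, ear_12_47, ear_48_59)
  )
}

#' Look up the EAR for each child
#'
#' @param age_months integer vector of ages in months (6-59).
#' @param sex character vector (`"M"`/`"F"`), recycled; only used when the
#'   table carries sex-specific rows.
#' @param ears an EAR table as returned by [default_ear_table()].
#' @return numeric vector of EAR cut-offs (ug RAE/day).
#' @export
ear_for <- function(age_months, sex = "any", ears = default_ear_table()) {
  sex <- rep_len(as.character(sex), length(age_months))
  out <- rep(NA_real_, length(age_months))
  for (i in seq_len(nrow(ears))) {
    row <- ears[i, ]
    hit <- age_months >= row$age_min & age_months <= row$age_max &
      (row$sex == "any" | sex == row$sex)
    out[hit] <- row$ear
  }
  if (anyNA(out)) {
    bad <- unique(paste0(age_months[is.na(out)], "mo/", sex[is.na(out)]))
    stop("no EAR bracket covers: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

# Bracket weights for a uniform age distribution over 6-59 months, used by the
# closed-form population calculations (6 months, 36 months, 12 months of the
# 54-month span).
ear_bracket_weights <- function(ears = default_ear_table()) {
  w <- (ears$age_max - ears$age_min + 1) / sum(ears$age_max - ears$age_min + 1)
  list(ear = ears$ear, weight = w)
}
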