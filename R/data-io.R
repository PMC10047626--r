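#' @importFrom rlang .data
NULL

# Enumerations of the coding scheme. state_factor values follow the
# high-state convention: positive correlations mean choosier when young /
# attractive / large / good-condition / mated / low-parasite.
mc_enums <- list(
  sex = c("female", "male"),
  state_factor = c("age", "attractiveness", "body_size", "condition",
                   "mating_status", "parasite_load"),
  state_variation = c("natural", "manipulated"),
  courter_interaction = c("physical", "behavioral_only", "no_live_mate"),
  data_type = c("correlation", "group_test", "group_means", "frequency"),
  high_state_direction = c("as_predicted", "reversed"),
  stat_kind = c("t", "F")
)

# Column order of the flat CSV schema. Exactly one raw-payload group is
# non-missing per row: r | stat_kind+stat_value(+stat_df)+n1+n2 |
# m1,sd1,n1,m2,sd2,n2 | a,b,c,d. For stat_kind = "F" the sign of
# stat_value carries the reported direction; its magnitude is F.
mc_schema_cols <- c(
  "record_id", "study_id", "species", "sex", "state_factor",
  "taxonomic_group", "state_variation", "courter_interaction", "data_type",
  "publication_year", "n_total", "high_state_direction", "directionless",
  "r", "stat_kind", "stat_value", "stat_df", "n1", "n2",
  "m1", "sd1", "m2", "sd2", "a", "b", "c", "d"
)

mc_payload_cols <- list(
  correlation = "r",
  group_test  = c("stat_kind", "stat_value", "n1", "n2"),
  group_means = c("m1", "sd1", "n1", "m2", "sd2", "n2"),
  frequency   = c("a", "b", "c", "d")
)

mc_col_types <- readr::cols(
  record_id = readr::col_character(),
  study_id = readr::col_character(),
  species = readr::col_character(),
  sex = readr::col_character(),
  state_factor = readr::col_character(),
  taxonomic_group = readr::col_character(),
  state_variation = readr::col_character(),
  courter_interaction = readr::col_character(),
  data_type = readr::col_character(),
  publication_year = readr::col_integer(),
  n_total = readr::col_integer(),
  high_state_direction = readr::col_character(),
  directionless = readr::col_logical(),
  r = readr::col_double(),
  stat_kind = readr::col_character(),
  stat_value = readr::col_double(),
  stat_df = readr::col_double(),
  n1 = readr::col_integer(),
  n2 = readr::col_integer(),
  m1 = readr::col_double(),
  sd1 = readr::col_double(),
  m2 = readr::col_double(),
  sd2 = readr::col_double(),
  a = readr::col_integer(),
  b = readr::col_integer(),
  c = readr::col_integer(),
  d = readr::col_integer()
)

validate_record_row <- function(row) {
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  chk(!is.na(row$record_id) && nzchar(row$record_id), "missing record_id")
  chk(!is.na(row$n_total) && row$n_total >= 4,
      "n_total must be >= 4 (variance 1/(n - 3) undefined)")
  for (col in names(mc_enums)[names(mc_enums) != "stat_kind"]) {
    val <- row[[col]]
    if (!is.null(val) && !is.na(val) && is.character(val)) {
      chk(val %in% mc_enums[[col]],
          paste0("unknown ", col, " value '", val, "'"))
    }
  }
  chk(row$sex %in% mc_enums$sex, "missing/invalid sex")
  chk(row$state_factor %in% mc_enums$state_factor, "missing/invalid state_factor")
  chk(row$data_type %in% mc_enums$data_type, "missing/invalid data_type")
  chk(isTRUE(row$directionless) || isFALSE(row$directionless),
      "directionless must be TRUE/FALSE")
  if (!isTRUE(row$directionless)) {
    chk(row$high_state_direction %in% mc_enums$high_state_direction,
        "missing/invalid high_state_direction")
  }

  if (isTRUE(row$data_type %in% names(mc_payload_cols))) {
    need <- mc_payload_cols[[row$data_type]]
    have <- !vapply(row[need], is.na, logical(1))
    chk(all(have), paste0("incomplete ", row$data_type, " payload (needs ",
                          paste(need, collapse = ", "), ")"))
    other <- setdiff(unlist(mc_payload_cols), c(need, "stat_df"))
    extra <- !vapply(row[other], is.na, logical(1))
    chk(!any(extra), "more than one raw-payload group filled")
    if (all(have)) {
      if (row$data_type == "correlation") {
        chk(abs(row$r) <= 1, "reported r outside [-1, 1]")
      } else if (row$data_type == "group_test") {
        chk(row$stat_kind %in% mc_enums$stat_kind, "stat_kind must be t or F")
        chk(row$n1 >= 2 && row$n2 >= 2, "group sizes must be >= 2")
        chk(row$n1 + row$n2 == row$n_total, "n1 + n2 must equal n_total")
      } else if (row$data_type == "group_means") {
        chk(row$sd1 >= 0 && row$sd2 >= 0, "SDs must be nonnegative")
        chk(row$sd1 > 0 || row$sd2 > 0, "both group SDs are zero")
        chk(row$n1 >= 2 && row$n2 >= 2, "group sizes must be >= 2")
        chk(row$n1 + row$n2 == row$n_total, "n1 + n2 must equal n_total")
      } else if (row$data_type == "frequency") {
        cells <- c(row$a, row$b, row$c, row$d)
        chk(all(cells >= 0), "negative cell count")
        chk(sum(cells) == row$n_total, "a+b+c+d must equal n_total")
        chk(all(c(row$a + row$b, row$c + row$d,
                  row$a + row$c, row$b + row$d) > 0),
            "zero margin in 2x2 table")
      }
    }
  }
  problems
}

#' Read and validate an effect-size table
#'
#' Reads the flat CSV schema (one row per extracted correlation; see
#' [write_effects()] for the column layout), validates every row, and
#' returns the valid records as a tibble. Structural problems (missing
#' mandatory columns) are errors; record-level problems (n_total < 4,
#' unknown enum values, malformed raw payloads) reject the offending rows,
#' which are reported in a warning and attached as the `"rejects"`
#' attribute (a tibble of row number, record_id, reason).
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated effect-size records, with attribute
#'   `"rejects"`.
#' @export
read_effects <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = mc_col_types,
                         na = c("", "NA"), progress = FALSE)
  missing_cols <- setdiff(mc_schema_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("Effect-size table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_effects(raw[mc_schema_cols])
}

#' @rdname read_effects
#' @param records A tibble already in the schema layout (e.g. simulated
#'   records), to be validated without touching disk.
#' @export
validate_effects <- function(records) {
  records <- tibble::as_tibble(records)
  records$species <- normalize_species(records$species)
  probs <- lapply(seq_len(nrow(records)), function(i) {
    validate_record_row(as.list(records[i, ]))
  })
  bad <- which(lengths(probs) > 0)
  rejects <- tibble::tibble(
    row = bad,
    record_id = records$record_id[bad],
    reason = vapply(probs[bad], paste, character(1), collapse = "; ")
  )
  if (length(bad) > 0) {
    warning(length(bad), " row(s) rejected during validation; see ",
            "attr(, 'rejects'). First: row ", rejects$row[1], " (",
            rejects$record_id[1], "): ", rejects$reason[1], call. = FALSE)
    records <- records[-bad, ]
  }
  if (anyDuplicated(records$record_id)) {
    stop("Duplicate record_id values: ",
         paste(unique(records$record_id[duplicated(records$record_id)]),
               collapse = ", "), call. = FALSE)
  }
  attr(records, "rejects") <- rejects
  records
}

#' Write an effect-size table
#'
#' Writes records (or simulated records) to the flat CSV schema: UTF-8,
#' comma-separated, one header row, raw payloads packed in typed columns
#' with exactly one group non-missing per row.
#'
#' @param records Tibble of effect-size records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(records, path) {
  for (col in setdiff(mc_schema_cols, names(records))) records[[col]] <- NA
  readr::write_csv(records[mc_schema_cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Convert validated records to coded Fisher-Z effects
#'
#' Each record's raw payload is converted to a signed correlation
#' (reported r, two-group test statistic, group summaries via Hedges' d,
#' or 2x2 frequency table via phi), oriented by the high-state sign
#' convention ([code_direction()]), and transformed to Fisher's Z with
#' sampling variance 1/(n_total - 3). Directionless records (nonsignificant
#' results reported without a direction) are coded Zr = 0 under the
#' `"full"` variant and dropped under `"reduced"`; either way their
#' variance stays 1/(n - 3).
#'
#' @param records Validated records from [read_effects()] /
#'   [validate_effects()].
#' @param variant `"full"` (keep directionless effects at zero) or
#'   `"reduced"` (drop them).
#' @return A tibble of coded effects: `record_id`, `zr`, `v`, `r`, plus all
#'   moderator fields.
#' @export
code_effects <- function(records, variant = c("full", "reduced")) {
  variant <- match.arg(variant)
  records <- tibble::as_tibble(records)

  raw_r <- vapply(seq_len(nrow(records)), function(i) {
    row <- as.list(records[i, ])
    if (isTRUE(row$directionless)) return(0)
    switch(row$data_type,
      correlation = clamp_r(row$r),
      group_test = if (row$stat_kind == "F") {
        test_stat_to_r(abs(row$stat_value), row$n1, row$n2, kind = "F",
                       direction = if (row$stat_value < 0) -1 else 1)
      } else {
        test_stat_to_r(row$stat_value, row$n1, row$n2, kind = "t")
      },
      group_means = d_to_r(
        hedges_d(row$m1, row$sd1, row$n1, row$m2, row$sd2, row$n2),
        row$n1, row$n2),
      frequency = clamp_r(freq_table_to_r(row$a, row$b, row$c, row$d))
    )
  }, numeric(1))

  dirless <- records$directionless
  r_coded <- raw_r
  r_coded[!dirless] <- code_direction(raw_r[!dirless],
                                      records$high_state_direction[!dirless])

  out <- dplyr::mutate(
    dplyr::select(records, dplyr::all_of(c(
      "record_id", "study_id", "species", "sex", "state_factor",
      "taxonomic_group", "state_variation", "courter_interaction",
      "data_type", "publication_year", "n_total", "directionless"))),
    r = r_coded,
    zr = fisher_z(r_coded),
    v = zr_variance(.data$n_total)
  )
  n_dirless <- sum(dirless)
  if (variant == "reduced") {
    out <- dplyr::filter(out, !.data$directionless)
    rlang::inform(paste0("Reduced dataset: dropped ", n_dirless,
                         " directionless effect(s); ", nrow(out), " retained."))
  } else {
    rlang::inform(paste0("Full dataset: ", nrow(out), " effects, of which ",
                         n_dirless, " directionless (coded Zr = 0)."))
  }
  out
}

#' Assemble a dataset: coded effects paired with a species tree
#'
#' Validates that every species in the effect table is a tip of the tree
#' (after name normalization), that a `"reduced"` dataset contains no
#' directionless effects, and stores the effect count `k`. The tree is
#' Grafen-calibrated if it is not already ultrametric.
#'
#' @param effects Coded effects from [code_effects()].
#' @param tree An [ape::phylo] species tree.
#' @param variant Which directionless-policy variant `effects` represents.
#' @return An object of class `mc_data`: a list with `effects`, `tree`,
#'   `variant`, `k`.
#' @export
build_dataset <- function(effects, tree, variant = c("full", "reduced")) {
  variant <- match.arg(variant)
  stopifnot(inherits(tree, "phylo"))
  effects <- tibble::as_tibble(effects)
  if (!all(c("zr", "v", "species", "study_id", "record_id") %in% names(effects))) {
    stop("effects must be coded (see code_effects()); need columns zr, v, ",
         "species, study_id, record_id.", call. = FALSE)
  }
  effects$species <- normalize_species(effects$species)
  tree$tip.label <- normalize_species(tree$tip.label)
  missing <- setdiff(unique(effects$species), tree$tip.label)
  if (length(missing) > 0) {
    stop("Species in the effect table but not in the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (variant == "reduced" && any(effects$directionless)) {
    stop("A reduced dataset must not contain directionless effects.",
         call. = FALSE)
  }
  if (is.null(tree$edge.length) ||
      !ape::is.ultrametric(tree, tol = 1e-8, option = 2)) {
    tree <- grafen_calibrate(tree)
  }
  structure(
    list(effects = effects, tree = tree, variant = variant,
         k = nrow(effects)),
    class = "mc_data"
  )
}

#' @export
print.mc_data <- function(x, ...) {
  cat("<mc_data> ", x$k, " coded effects (", x$variant, " variant), ",
      length(unique(x$effects$species)), " species, ",
      length(unique(x$effects$study_id)), " studies; tree with ",
      ape::Ntip(x$tree), " tips\n", sep = "")
  invisible(x)
}
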