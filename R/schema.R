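#' Default 34-feature stroke screening schema
#'
#' Returns the feature dictionary used throughout the package: one row per
#' feature with its abbreviation, kind (`binary`, `ordinal`, `continuous`),
#' allowed integer codes for categorical features, a plausible value range
#' for continuous features, and the clinical normal band where one is
#' defined. The dictionary covers the standard screening variables (blood
#' pressures, lipids, glycaemic markers, lifestyle and history flags); the
#' features marked `filler = TRUE` round the table out to the 34 columns a
#' screening registry export carries and use plausible but generic codings.
#'
#' Smoking (`Sm`) is coded 2 = current, 1 = quit, 0 = never; years of
#' smoking (`Ys`) is only defined for ever-smokers and is zero otherwise.
#'
#' @return A tibble with columns `name`, `kind`, `codes` (list column of
#'   integer vectors, `NULL` for continuous), `range` (list column of
#'   length-2 numeric, `NULL` for categorical), `normal_range` (list column,
#'   `NULL` when no clinical band applies), and `filler`.
#' @examples
#' sch <- default_schema()
#' nrow(sch)                       # 34
#' schema_feature(sch, "Sm")$codes # 0, 1, 2
#' @export
default_schema <- function() {
  bin <- function(name, label, filler = FALSE) {
    tibble::tibble(
      name = name, label = label, kind = "binary",
      codes = list(c(0L, 1L)), range = list(NULL),
      normal_range = list(NULL), filler = filler
    )
  }
  ord <- function(name, label, codes, filler = FALSE) {
    tibble::tibble(
      name = name, label = label, kind = "ordinal",
      codes = list(as.integer(codes)), range = list(NULL),
      normal_range = list(NULL), filler = filler
    )
  }
  cont <- function(name, label, range, normal = NULL, filler = FALSE) {
    tibble::tibble(
      name = name, label = label, kind = "continuous",
      codes = list(NULL), range = list(range),
      normal_range = list(normal), filler = filler
    )
  }
  sch <- dplyr::bind_rows(
    bin("Arhm", "arrhythmia"),
    cont("BMI", "body mass index", c(15, 40), c(20, 25)),
    ord("Edu", "education level", 1:5),
    bin("Exs", "lack of exercise"),
    cont("FA", "filling age", c(18, 95)),
    cont("FBG", "fasting blood glucose (mmol/L)", c(2.5, 15), c(3.9, 6.1)),
    cont("HbA1c", "glycosylated hemoglobin (%)", c(3, 14), c(4, 6)),
    cont("Hcy", "homocysteine (umol/L)", c(3, 40), c(5, 15)),
    # pooled male/female band
    cont("HDL-C", "HDL cholesterol (mmol/L)", c(0.5, 3), c(1.16, 1.55)),
    bin("HEH", "history of hypertension"),
    bin("HS", "history of stroke"),
    cont("Ht", "height (cm)", c(140, 195)),
    cont("Wt", "weight (kg)", c(40, 120)),
    cont("LDBP", "left diastolic blood pressure (mmHg)", c(40, 130), c(60, 89)),
    cont("LDL-C", "LDL cholesterol (mmol/L)", c(0.4, 6.5), c(0.5, 3.37)),
    cont("LSBP", "left systolic blood pressure (mmHg)", c(70, 220), c(80, 140)),
    ord("MV", "meat/vegetable balance", 1:3),
    bin("Ret", "retired"),
    ord("Sm", "smoking status (2 yes, 1 quit, 0 no)", 0:2),
    cont("TC", "total cholesterol (mmol/L)", c(2, 10), c(3, 5.2)),
    cont("TG", "triglyceride (mmol/L)", c(0.3, 6), c(0.6, 1.7)),
    cont("Ys", "years of smoking (0 for never-smokers)", c(0, 60)),
    # right-arm pressures: coded like their left-arm counterparts
    cont("RSBP", "right systolic blood pressure (mmHg)", c(70, 220), c(80, 140)),
    cont("RDBP", "right diastolic blood pressure (mmHg)", c(40, 130), c(60, 89)),
    bin("Sex", "sex (1 male, 0 female)"),
    cont("Age", "age (years)", c(18, 95)),
    # documented filler: plausible registry columns completing the 34
    bin("FHS", "family history of stroke", filler = TRUE),
    bin("Flv", "light-flavour diet", filler = TRUE),
    bin("Alc", "regular alcohol use", filler = TRUE),
    bin("Dbt", "history of diabetes", filler = TRUE),
    bin("HLP", "history of hyperlipidemia", filler = TRUE),
    bin("CHD", "history of coronary heart disease", filler = TRUE),
    bin("AF", "atrial fibrillation ever recorded", filler = TRUE),
    ord("Slt", "salt intake (1 low, 2 medium, 3 high)", 1:3, filler = TRUE)
  )
  validate_schema(sch)
  sch
}

#' Look up one feature of a schema
#'
#' @param schema A schema tibble from [default_schema()].
#' @param name Feature abbreviation.
#' @return A one-row list with `name`, `kind`, `codes`, `range`,
#'   `normal_range`.
#' @export
schema_feature <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) stop("unknown feature: ", name, call. = FALSE)
  list(
    name = schema$name[i], kind = schema$kind[i],
    codes = schema$codes[[i]], range = schema$range[[i]],
    normal_range = schema$normal_range[[i]]
  )
}

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema))
  if (anyDuplicated(schema$name) > 0) {
    stop("schema names must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(schema))) {
    kind <- schema$kind[i]
    if (kind == "continuous") {
      r <- schema$range[[i]]
      if (is.null(r) || length(r) != 2 || r[1] >= r[2]) {
        stop("continuous feature ", schema$name[i],
             " needs range with low < high", call. = FALSE)
      }
      nr <- schema$normal_range[[i]]
      if (!is.null(nr) && (nr[1] < r[1] || nr[2] > r[2])) {
        stop("normal_range of ", schema$name[i],
             " must lie inside range", call. = FALSE)
      }
    } else {
      codes <- schema$codes[[i]]
      if (is.null(codes) || length(codes) < 2) {
        stop("categorical feature ", schema$name[i], " needs >= 2 codes",
             call. = FALSE)
      }
      if (kind == "binary" && !all(codes %in% 0:2)) {
        stop("binary feature ", schema$name[i], " has unexpected codes",
             call. = FALSE)
      }
    }
  }
  invisible(schema)
}

#' Write / read a schema as YAML
#'
#' @param schema Schema tibble.
#' @param path File path.
#' @return `read_schema()` returns the schema tibble; `write_schema()`
#'   returns `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  entries <- purrr::pmap(schema, function(name, label, kind, codes, range,
                                          normal_range, filler) {
    x <- list(name = name, label = label, kind = kind, filler = filler)
    if (!is.null(codes)) x$codes <- as.integer(codes)
    if (!is.null(range)) x$range <- as.numeric(range)
    if (!is.null(normal_range)) x$normal_range <- as.numeric(normal_range)
    x
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  entries <- yaml::read_yaml(path)
  sch <- dplyr::bind_rows(purrr::map(entries, function(e) {
    tibble::tibble(
      name = e$name, label = e$label %||% e$name, kind = e$kind,
      codes = list(if (is.null(e$codes)) NULL else as.integer(e$codes)),
      range = list(if (is.null(e$range)) NULL else as.numeric(e$range)),
      normal_range = list(
        if (is.null(e$normal_range)) NULL else as.numeric(e$normal_range)
      ),
      filler = isTRUE(e$filler)
    )
  }))
  validate_schema(sch)
  sch
}
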