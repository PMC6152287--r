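#' Registry of the 21 measured parameters
#'
#' The study measures 21 anthropometric and biochemical parameters per
#' subject, conventionally numbered w1..w21.  Five of them (urinary albumin,
#' insulin, HOMA-IR, the insulin sensitivity index and the beta-cell function
#' index) are right-skewed and are summarised by median and quartiles rather
#' than mean and SD; the catalog records this as a `lognormal` marginal
#' family, `normal` for all others.
#'
#' @return A data frame of class `parameter_catalog` with columns `index`
#'   (1..21), `code` (`"w1"`..`"w21"`), `name`, `units` and `family`
#'   (`"normal"` or `"lognormal"`).
#' @examples
#' cat21 <- parameter_catalog()
#' subset(cat21, family == "lognormal")$code
#' @export
parameter_catalog <- function() {
  defs <- list(
    list(1L,  "weight",        "Body weight",                          "kg",      "normal"),
    list(2L,  "bmi",           "Body mass index",                      "kg/m2",   "normal"),
    list(3L,  "waist",         "Waist circumference",                  "cm",      "normal"),
    list(4L,  "hips",          "Hip circumference",                    "cm",      "normal"),
    list(5L,  "whr_age",       "Waist-hip ratio (age-referenced)",     "ratio",   "normal"),
    list(6L,  "whr",           "Waist-hip ratio (unreferenced)",       "ratio",   "normal"),
    list(7L,  "hba1c",         "Glycated haemoglobin",                 "%",       "normal"),
    list(8L,  "chol_total",    "Total cholesterol",                    "mg/dL",   "normal"),
    list(9L,  "chol_hdl",      "HDL cholesterol",                      "mg/dL",   "normal"),
    list(10L, "chol_ldl",      "LDL cholesterol",                      "mg/dL",   "normal"),
    list(11L, "triglycerides", "Triacylglycerols",                     "mg/dL",   "normal"),
    list(12L, "creatinine",    "Serum creatinine",                     "mg/dL",   "normal"),
    list(13L, "alb_urine",     "Albumin in urine",                     "ug/mL",   "lognormal"),
    list(14L, "glucose",       "Fasting glucose",                      "mg/dL",   "normal"),
    list(15L, "insulin",       "Fasting insulin",                      "uIU/mL",  "lognormal"),
    list(16L, "homa_ir",       "HOMA insulin-resistance index",        "index",   "lognormal"),
    list(17L, "homa_s",        "Insulin sensitivity index (%S)",       "%",       "lognormal"),
    list(18L, "homa_b",        "Beta-cell function index (%B)",        "%",       "lognormal"),
    list(19L, "sobr",          "Soluble leptin receptor",              "ng/mL",   "normal"),
    list(20L, "leptin",        "Plasma leptin",                        "ng/mL",   "normal"),
    list(21L, "adiponectin",   "Plasma adiponectin",                   "ug/mL",   "normal")
  )
  out <- data.frame(
    index  = vapply(defs, `[[`, integer(1), 1L),
    code   = paste0("w", seq_along(defs)),
    short  = vapply(defs, `[[`, character(1), 2L),
    name   = vapply(defs, `[[`, character(1), 3L),
    units  = vapply(defs, `[[`, character(1), 4L),
    family = vapply(defs, `[[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
  class(out) <- c("parameter_catalog", "data.frame")
  out
}

# parameters that must be strictly positive in any valid record:
# all lognormal-family parameters plus weight, BMI, circumferences, the
# WHR ratios and HbA1c.  (Other normal-family analytes such as creatinine
# may in principle take small simulated values near zero.)
positive_parameters <- function(catalog) {
  sort(unique(c(1:7, catalog$index[catalog$family == "lognormal"])))
}

assert_catalog <- function(catalog) {
  if (!inherits(catalog, "parameter_catalog")) {
    stop("`catalog` must be a parameter_catalog (see parameter_catalog())",
         call. = FALSE)
  }
  if (nrow(catalog) != 21L || !identical(catalog$index, 1:21)) {
    stop("catalog must contain indices 1..21 exactly once, in order",
         call. = FALSE)
  }
  lg <- catalog$index[catalog$family == "lognormal"]
  if (!identical(lg, c(13L, 15:18))) {
    stop("lognormal family must be exactly parameters 13, 15, 16, 17, 18",
         call. = FALSE)
  }
  invisible(catalog)
}
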