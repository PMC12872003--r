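#' @keywords internal
"_PACKAGE"

# Canonical category levels shared across the package.
LSM_ARMS <- c("intervention", "control")
LSM_PHASES <- c("mapping", "spraying", "combined")
LSM_GENERA <- c("Anopheles", "Aedes", "Culex", "Mansonia", "non_target")
LSM_SEXES <- c("male", "female", "unknown")
WATERBODY_LEVELS <- list(
  waterbody_type = c(
    "drainage ditches", "swampy area", "reservoir", "puddle made by rain",
    "rice paddy", "upland rice field", "other agricultural field"
  ),
  origin = c("artificial", "natural"),
  area_size_class = c("very_small", "small", "medium", "large"),
  vegetation_inside = c("FALSE", "TRUE"),
  vegetation_around = c("FALSE", "TRUE"),
  visual_turbidity = c("clean", "turbid", "very turbid")
)

# Declarative schema registry: column names, parsers and row invariants.
# Each check returns NULL when fine, or a message naming the violation.
lsm_schemas <- function() {
  list(
    subdistrict = list(
      columns = c("name", "arm", "population", "area_km2", "lsm_start_month"),
      parse = function(df) {
        df$population <- as.integer(df$population)
        df$area_km2 <- as.numeric(df$area_km2)
        df
      },
      check = function(row) {
        if (!row$arm %in% LSM_ARMS) {
          return(sprintf("arm '%s' is not one of %s", row$arm,
                         paste(LSM_ARMS, collapse = "/")))
        }
        if (is.na(row$population) || row$population <= 0) {
          return("population must be a positive integer")
        }
        if (is.na(row$area_km2) || row$area_km2 <= 0) {
          return("area_km2 must be > 0")
        }
        NULL
      }
    ),
    workphase = list(
      columns = c("sub_district", "phase", "workers", "days"),
      parse = function(df) {
        df$workers <- as.integer(df$workers)
        df$days <- as.integer(df$days)
        df
      },
      check = function(row) {
        if (!row$phase %in% LSM_PHASES) {
          return(sprintf("phase '%s' is not one of %s", row$phase,
                         paste(LSM_PHASES, collapse = "/")))
        }
        if (is.na(row$workers) || row$workers < 1) return("workers must be >= 1")
        if (is.na(row$days) || row$days < 1) return("days must be >= 1")
        NULL
      }
    ),
    spraylog = list(
      columns = c("sub_district", "found_sites", "sprayed_sites",
                  "packs_per_month"),
      parse = function(df) {
        df$found_sites <- as.integer(df$found_sites)
        df$sprayed_sites <- as.integer(df$sprayed_sites)
        df$packs_per_month <- as.numeric(df$packs_per_month)
        df
      },
      check = function(row) {
        if (is.na(row$found_sites) || row$found_sites < 0) {
          return("found_sites must be >= 0")
        }
        if (is.na(row$sprayed_sites) || row$sprayed_sites < 0 ||
            row$sprayed_sites > row$found_sites) {
          return("sprayed_sites must satisfy 0 <= sprayed_sites <= found_sites")
        }
        if (is.na(row$packs_per_month) || row$packs_per_month <= 0) {
          return("packs_per_month must be > 0")
        }
        NULL
      }
    ),
    detection = list(
      columns = c("sub_district", "sites_drone", "sites_manual"),
      parse = function(df) {
        df$sites_drone <- as.integer(df$sites_drone)
        df$sites_manual <- as.integer(df$sites_manual)
        df
      },
      check = function(row) {
        if (is.na(row$sites_drone) || row$sites_drone < 0) {
          return("sites_drone must be >= 0")
        }
        if (is.na(row$sites_manual) || row$sites_manual < 0) {
          return("sites_manual must be >= 0")
        }
        NULL
      }
    ),
    trapcatch = list(
      columns = c("site", "week_index", "genus", "sex", "count"),
      parse = function(df) {
        df$week_index <- as.integer(df$week_index)
        df$count <- as.integer(df$count)
        df
      },
      check = function(row) {
        if (!row$genus %in% LSM_GENERA) {
          return(sprintf("genus '%s' is not one of %s", row$genus,
                         paste(LSM_GENERA, collapse = "/")))
        }
        if (!row$sex %in% LSM_SEXES) {
          return(sprintf("sex '%s' is not one of %s", row$sex,
                         paste(LSM_SEXES, collapse = "/")))
        }
        if (is.na(row$week_index) || row$week_index < 1) {
          return("week_index must be >= 1")
        }
        if (is.na(row$count) || row$count < 0) return("count must be >= 0")
        NULL
      }
    ),
    waterbody = list(
      columns = c("id", "waterbody_type", "origin", "area_size_class",
                  "vegetation_inside", "vegetation_around", "visual_turbidity"),
      optional = "larvae_present",
      parse = function(df) {
        df$vegetation_inside <- as.logical(df$vegetation_inside)
        df$vegetation_around <- as.logical(df$vegetation_around)
        if ("larvae_present" %in% names(df)) {
          df$larvae_present <- as.integer(df$larvae_present)
        }
        df
      },
      check = function(row) {
        for (f in c("waterbody_type", "origin", "area_size_class",
                    "visual_turbidity")) {
          if (!as.character(row[[f]]) %in% WATERBODY_LEVELS[[f]]) {
            return(sprintf("%s '%s' is not an allowed level", f, row[[f]]))
          }
        }
        if (is.na(row$vegetation_inside) || is.na(row$vegetation_around)) {
          return("vegetation flags must be TRUE/FALSE")
        }
        if (!is.null(row$larvae_present) && !is.na(row$larvae_present) &&
            !row$larvae_present %in% c(0L, 1L)) {
          return("larvae_present must be 0 or 1")
        }
        NULL
      }
    )
  )
}

validate_schema_df <- function(df, schema_name) {
  sc <- lsm_schemas()[[schema_name]]
  if (is.null(sc)) stop("unknown schema: ", schema_name, call. = FALSE)
  missing <- setdiff(sc$columns, names(df))
  if (length(missing)) {
    stop(sprintf("schema '%s': missing column(s) %s", schema_name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- sc$parse(df)
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      msg <- sc$check(as.list(df[i, , drop = FALSE]))
      if (!is.null(msg)) {
        stop(sprintf("schema '%s': row %d: %s", schema_name, i, msg),
             call. = FALSE)
      }
    }
  }
  keep <- c(sc$columns, intersect(sc$optional %||% character(), names(df)))
  df[, keep, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a typed LSM table from CSV
#'
#' Reads a comma-separated file (UTF-8, mandatory header) and validates every
#' row against one of the package's record schemas: `"subdistrict"`
#' (administrative unit of comparison), `"workphase"` (workers x days per
#' field phase), `"spraylog"` (found/sprayed sites and larvicide packs),
#' `"detection"` (drone vs manual scouting counts), `"trapcatch"` (CDC
#' light-trap records) or `"waterbody"` (the six categorical habitat
#' features, with an optional `larvae_present` label column).
#'
#' @param path Path to a CSV file whose header matches the schema's fields.
#' @param schema One of `"subdistrict"`, `"workphase"`, `"spraylog"`,
#'   `"detection"`, `"trapcatch"`, `"waterbody"`.
#' @return A `data.frame` with typed columns, rows in file order. An empty
#'   file with a valid header yields a zero-row frame.
#' @seealso [write_lsm_table()], [load_paper_fixtures()]
#' @export
#' @examples
#' f <- system.file("extdata", "subdistricts.csv", package = "lsmeval")
#' sd <- read_lsm_table(f, "subdistrict")
#' sum(sd$area_km2[sd$arm == "intervention"])
read_lsm_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  validate_schema_df(df, schema)
}

#' Write a typed LSM table to CSV
#'
#' Validates the records against `schema` and writes them so that
#' `read_lsm_table(write_lsm_table(x, ...), schema)` is the identity.
#'
#' @param records A data.frame of records sharing one schema.
#' @inheritParams read_lsm_table
#' @return `path`, invisibly.
#' @export
write_lsm_table <- function(records, path, schema) {
  records <- validate_schema_df(records, schema)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
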