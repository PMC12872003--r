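# Shared helpers: independent oracles and small data builders.

FEATURE_COLS <- c("waterbody_type", "origin", "area_size_class",
                  "vegetation_inside", "vegetation_around",
                  "visual_turbidity")

# Independent Mann-Whitney oracle: U by direct pairwise comparison counting
# (not rank sums), exact p by enumerating every assignment of the combined
# values to the first group.
mw_oracle <- function(a, b) {
  comb <- c(a, b)
  n1 <- length(a)
  n2 <- length(b)
  u_of <- function(ai) {
    av <- comb[ai]
    bv <- comb[-ai]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  idx <- utils::combn(length(comb), n1)
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                      mean(u_all >= u_obs - eps)))
  list(u = min(u_obs, n1 * n2 - u_obs), p = p)
}

# Term-by-term Pearson chi-square oracle with explicit loops.
chisq_oracle <- function(m) {
  total <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / total
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  stat
}

# Toy feature frame where risk is a deterministic function of turbidity.
toy_waterbodies <- function(n, seed = 99) {
  lv <- list(
    waterbody_type = c("drainage ditches", "swampy area", "reservoir",
                       "puddle made by rain", "rice paddy",
                       "upland rice field", "other agricultural field"),
    origin = c("artificial", "natural"),
    area_size_class = c("very_small", "small", "medium", "large"),
    visual_turbidity = c("clean", "turbid", "very turbid")
  )
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    code
  }
  withr_seed({
    df <- data.frame(
      waterbody_type = sample(lv$waterbody_type, n, TRUE),
      origin = sample(lv$origin, n, TRUE),
      area_size_class = sample(lv$area_size_class, n, TRUE),
      vegetation_inside = sample(c(TRUE, FALSE), n, TRUE),
      vegetation_around = sample(c(TRUE, FALSE), n, TRUE),
      visual_turbidity = sample(lv$visual_turbidity, n, TRUE),
      stringsAsFactors = FALSE
    )
    df$larvae_present <- as.integer(df$visual_turbidity == "very turbid")
    df
  })
}

paper_tpdua_intervention <- c(2.82, 2.99, 4.85, 5.32)
paper_tpdua_control <- c(5.41, 6.72, 7.74, 12.24)
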