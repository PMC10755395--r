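# Small deterministic fixtures built in code.

# A hand-written catalogue: product A is a 500 ml drink at 42 kcal/100 ml,
# B has no profile (category 7), C is a 1000 g loose-weight item, D is a
# per-unit item.
tiny_catalogue <- function() {
  tibble::tibble(
    product_id = c("A", "B", "C", "D"),
    description = c("fizzy drink", "bakery roll", "loose potatoes", "pies"),
    category = c(3L, 7L, 2L, 7L),
    pack_amount = c(500, 400, 1000, 1),
    pack_unit = c("ml", "g", "g", "each"),
    unit_net_weight_g = c(NA, NA, NA, 150),
    price = c(1, 1, 1, 2),
    staple = FALSE,
    per100_energy_kcal = c(42, NA, 80, 300),
    per100_sugars_g = c(10.5, NA, 1, 3),
    per100_protein_g = c(0, NA, 2, 10),
    per100_fat_g = c(0, NA, 0.1, 18),
    per100_satfat_g = c(0, NA, 0.02, 8),
    per100_sodium_mg = c(20, NA, 10, 500)
  )
}

# Generics over all 15 categories with distinct, easily recognised values.
tiny_generics <- function() {
  k <- 1:15
  tibble::tibble(
    category = k,
    per100_energy_kcal = 100 + 10 * k,
    per100_sugars_g = 2 + k / 10,
    per100_protein_g = 3 + k / 10,
    per100_fat_g = 4 + k / 10,
    per100_satfat_g = 1 + k / 20,
    per100_sodium_mg = 50 + 5 * k
  )
}

tx_line <- function(id, date, product, qty, customer = "ID1", cost = 1) {
  tibble::tibble(customer_id = customer, transaction_id = id,
                 date = as.Date(date), product_id = product,
                 quantity = qty, cost = cost)
}

# Random valid nutrient vector (energy consistent with macro bound).
random_nutrient_vector <- function() {
  e <- stats::runif(1, 500, 4000)
  fat <- stats::runif(1, 0, e / 9 * 0.4)
  nutrient_vector(
    energy_kcal = e,
    sugars_g = stats::runif(1, 0, e / 3.9 * 0.3),
    protein_g = stats::runif(1, 0, e / 4 * 0.2),
    fat_g = fat,
    satfat_g = stats::runif(1, 0, fat),
    sodium_mg = stats::runif(1, 0, 2.5 * e)
  )
}

# Cache expensive shared simulations across test files.
fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}
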