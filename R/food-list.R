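#' Default 60-item food list
#'
#' A synthetic food list mirroring the structure of a 7-day HCES food module:
#' 60 food items/groups with a reporting unit each (`kg`, `g`, `L`, `mL` or
#' `pieces`), flags for the three fortification vehicles (cooking oil, wheat
#' flour, maize flour), processed products that embed vehicles via recipes
#' (bread, buns/cakes/biscuits, sweets; macaroni/spaghetti is deliberately
#' recipe-less), and two concatenated items whose composition is a
#' frequency-weighted mean of components.
#'
#' @return A tibble with one row per food item: `food_code`, `food_name`,
#'   `food_group`, `report_unit`, `vehicle` (NA or one of
#'   [vehicle_names()]), `product_code` (NA or a recipe product label) and
#'   `is_composite`.
#' @export
default_food_list <- function() {
  fl <- master_food_table()
  fl[, c("food_code", "food_name", "food_group", "report_unit",
         "vehicle", "product_code", "is_composite")]
}

# One master table holding list structure, refuse/density/portion data and
# per-100 g edible-portion composition (synthetic, loosely FCT-plausible,
# scaled so national per-AFE intake distributions sit at the study's
# reported operating point). Composite items (501, 603) carry NA nutrient
# values here; generate_fixtures() fills them from component entries.
master_food_table <- function() {
  tb <- tibble::tribble(
    ~food_code, ~food_name, ~food_group, ~report_unit, ~vehicle, ~product_code, ~refuse_fraction, ~density_g_ml, ~portion_g, ~energy_kcal, ~iron_mg, ~zinc_mg, ~vita_rae_mcg, ~retinol_mcg, ~folate_mcg_dfe, ~vitb12_mcg, ~source_fct,
    101L, "Rice (husked)", "cereals", "kg", NA, NA, 0, NA, NA, 360, 0.6, 1.1, 0, 0, 9, 0, "KE18",
    102L, "Rice (paddy)", "cereals", "kg", NA, NA, 0.20, NA, NA, 350, 0.8, 1.2, 0, 0, 9, 0, "KE18",
    103L, "Maize (green, cob)", "cereals", "pieces", NA, NA, 0.45, NA, 220, 150, 0.9, 0.9, 7, 0, 42, 0, "KE18",
    104L, "Maize (grain)", "cereals", "kg", NA, NA, 0, NA, NA, 356, 2.7, 2.2, 5, 0, 25, 0, "KE18",
    105L, "Maize (flour)", "cereals", "kg", "maize_flour", NA, 0, NA, NA, 353, 2.4, 1.8, 0, 0, 25, 0, "KE18",
    106L, "Millet and sorghum (grain)", "cereals", "kg", NA, NA, 0, NA, NA, 340, 3.9, 2.3, 8, 0, 40, 0, "WA19",
    107L, "Millet and sorghum (flour)", "cereals", "kg", NA, NA, 0, NA, NA, 345, 3.5, 2.1, 5, 0, 35, 0, "WA19",
    108L, "Wheat flour", "cereals", "kg", "wheat_flour", NA, 0, NA, NA, 348, 1.5, 0.8, 0, 0, 26, 0, "KE18",
    109L, "Bread", "cereals", "pieces", NA, "bread", 0, NA, 400, 260, 1.2, 0.7, 0, 0, 24, 0, "KE18",
    110L, "Buns, cakes and biscuits", "cereals", "pieces", NA, "buns_cakes_biscuits", 0, NA, 60, 390, 1.3, 0.7, 15, 10, 25, 0.05, "US28",
    111L, "Macaroni and spaghetti", "cereals", "kg", NA, "macaroni", 0, NA, NA, 360, 1.2, 1.0, 0, 0, 18, 0, "US28",
    112L, "Other cereal products", "cereals", "kg", NA, NA, 0, NA, NA, 350, 1.8, 1.5, 0, 0, 20, 0, "WA19",
    201L, "Cassava (fresh)", "roots", "kg", NA, NA, 0.16, NA, NA, 150, 0.6, 0.4, 1, 0, 24, 0, "KE18",
    202L, "Cassava (dry or flour)", "roots", "kg", NA, NA, 0, NA, NA, 340, 1.9, 0.7, 0, 0, 28, 0, "WA19",
    203L, "Sweet potatoes", "roots", "kg", NA, NA, 0.12, NA, NA, 105, 0.7, 0.3, 30, 0, 12, 0, "KE18",
    204L, "Irish potatoes", "roots", "kg", NA, NA, 0.10, NA, NA, 77, 0.5, 0.3, 0, 0, 15, 0, "KE18",
    205L, "Cooking bananas (plantains)", "roots", "kg", NA, NA, 0.35, NA, NA, 122, 0.6, 0.2, 40, 0, 22, 0, "KE18",
    206L, "Yams and other starches", "roots", "kg", NA, NA, 0.14, NA, NA, 118, 0.6, 0.3, 3, 0, 20, 0, "WA19",
    301L, "Sugar", "sugars", "kg", NA, NA, 0, NA, NA, 387, 0.1, 0, 0, 0, 0, 0, "US28",
    302L, "Sweets", "sugars", "pieces", NA, "sweets", 0, NA, 25, 420, 0.5, 0.3, 0, 0, 8, 0, "US28",
    303L, "Honey and other sugar products", "sugars", "g", NA, NA, 0, NA, NA, 304, 0.4, 0.2, 0, 0, 2, 0, "US28",
    401L, "Beans (dry)", "pulses", "kg", NA, NA, 0, NA, NA, 341, 6.5, 2.8, 0, 0, 394, 0, "KE18",
    402L, "Peas and other pulses", "pulses", "kg", NA, NA, 0, NA, NA, 343, 4.8, 3.0, 2, 0, 274, 0, "KE18",
    403L, "Groundnuts", "pulses", "kg", NA, NA, 0, NA, NA, 567, 4.6, 3.3, 0, 0, 240, 0, "KE18",
    404L, "Coconut", "pulses", "pieces", NA, NA, 0.48, NA, 450, 354, 2.4, 1.1, 0, 0, 26, 0, "WA19",
    405L, "Cashew and other nuts", "pulses", "g", NA, NA, 0, NA, NA, 553, 6.7, 5.8, 0, 0, 25, 0, "US28",
    501L, "Onions, tomatoes, carrots and green peppers, other viungo", "vegetables", "kg", NA, NA, 0.06, NA, NA, NA, NA, NA, NA, NA, NA, NA, "composite",
    502L, "Spinach, cabbage and other green vegetables", "vegetables", "kg", NA, NA, 0.20, NA, NA, 33, 2.5, 0.5, 230, 0, 120, 0, "KE18",
    503L, "Dried and canned vegetables", "vegetables", "g", NA, NA, 0, NA, NA, 260, 5.0, 1.5, 300, 0, 80, 0, "WA19",
    601L, "Ripe bananas", "fruits", "pieces", NA, NA, 0.36, NA, 120, 89, 0.3, 0.2, 3, 0, 20, 0, "KE18",
    602L, "Citrus fruits", "fruits", "pieces", NA, NA, 0.30, NA, 150, 47, 0.3, 0.1, 11, 0, 30, 0, "KE18",
    603L, "Mangoes, avocados and other fruits", "fruits", "kg", NA, NA, 0.28, NA, NA, NA, NA, NA, NA, NA, NA, NA, "composite",
    604L, "Sugarcane", "fruits", "kg", NA, NA, 0.40, NA, NA, 60, 0.4, 0.1, 0, 0, 4, 0, "WA19",
    605L, "Dried fruits", "fruits", "g", NA, NA, 0, NA, NA, 280, 1.8, 0.4, 10, 0, 8, 0, "US28",
    701L, "Beef and beef products", "meat", "kg", NA, NA, 0, NA, NA, 217, 2.6, 4.8, 3, 3, 6, 2.6, "KE18",
    702L, "Goat and sheep meat", "meat", "kg", NA, NA, 0, NA, NA, 143, 2.8, 4.0, 0, 0, 5, 1.2, "KE18",
    703L, "Pork and pork products", "meat", "kg", NA, NA, 0, NA, NA, 242, 0.9, 2.4, 2, 2, 5, 0.7, "KE18",
    704L, "Chicken and other poultry", "meat", "kg", NA, NA, 0.35, NA, NA, 215, 1.3, 1.8, 16, 16, 6, 0.3, "KE18",
    705L, "Wild birds and insects", "meat", "g", NA, NA, 0, NA, NA, 300, 6.0, 7.0, 10, 10, 30, 1.0, "TZ08",
    706L, "Other meat products", "meat", "g", NA, NA, 0, NA, NA, 250, 2.5, 3.5, 5, 5, 5, 1.5, "WA19",
    707L, "Eggs", "meat", "pieces", NA, NA, 0.12, NA, 50, 143, 1.8, 1.3, 140, 140, 47, 0.9, "KE18",
    801L, "Fresh fish and shellfish", "fish", "kg", NA, NA, 0.35, NA, NA, 120, 1.0, 0.8, 15, 15, 10, 1.8, "KE18",
    802L, "Dried or salted fish and shellfish", "fish", "g", NA, NA, 0, NA, NA, 305, 6.6, 3.0, 30, 30, 25, 6.5, "KE18",
    803L, "Canned fish and shellfish", "fish", "g", NA, NA, 0, NA, NA, 190, 1.4, 0.9, 20, 20, 12, 2.5, "US28",
    804L, "Packaged fish products", "fish", "g", NA, NA, 0, NA, NA, 180, 1.2, 0.8, 15, 15, 10, 2.0, "US28",
    901L, "Fresh milk", "dairy", "L", NA, NA, 0, 1.03, NA, 61, 0.1, 0.4, 46, 46, 5, 0.4, "KE18",
    902L, "Canned and powdered milk", "dairy", "g", NA, NA, 0, NA, NA, 490, 0.5, 3.3, 250, 250, 37, 1.9, "US28",
    903L, "Cheese, yoghurt and other dairy", "dairy", "g", NA, NA, 0, NA, NA, 90, 0.1, 0.6, 40, 40, 7, 0.5, "US28",
    1001L, "Cooking oil", "fats", "L", "cooking_oil", NA, 0, 0.92, NA, 884, 0, 0, 0, 0, 0, 0, "KE18",
    1002L, "Butter, ghee and margarine", "fats", "g", NA, NA, 0, NA, NA, 717, 0, 0.1, 600, 600, 3, 0.1, "US28",
    1003L, "Other fats and oils", "fats", "g", NA, NA, 0, NA, NA, 800, 0, 0, 100, 100, 0, 0, "WA19",
    1101L, "Tea (dry)", "beverages", "g", NA, NA, 0, NA, NA, 300, 15, 2.0, 0, 0, 0, 0, "TZ08",
    1102L, "Coffee and cocoa", "beverages", "g", NA, NA, 0, NA, NA, 350, 5.0, 1.0, 0, 0, 0, 0, "TZ08",
    1103L, "Soft drinks and juices", "beverages", "L", NA, NA, 0, 1.04, NA, 40, 0, 0, 0, 0, 0, 0, "US28",
    1104L, "Bottled water", "beverages", "L", NA, NA, 0, 1.00, NA, 0, 0, 0, 0, 0, 0, 0, "US28",
    1105L, "Local brews", "beverages", "L", NA, NA, 0, 1.01, NA, 35, 0.5, 0.1, 1, 0, 5, 0, "TZ08",
    1106L, "Bottled beer", "beverages", "L", NA, NA, 0, 1.01, NA, 43, 0, 0, 0, 0, 6, 0, "US28",
    1107L, "Wine and spirits", "beverages", "L", NA, NA, 0, 0.95, NA, 150, 0.3, 0, 0, 0, 0, 0, "US28",
    1201L, "Salt", "condiments", "g", NA, NA, 0, NA, NA, 0, 0, 0, 0, 0, 0, 0, "US28",
    1202L, "Spices and other condiments", "condiments", "g", NA, NA, 0, NA, NA, 270, 10, 2.5, 30, 0, 40, 0, "WA19"
  )
  tb$is_composite <- tb$source_fct == "composite"
  tb$folic_acid_mcg <- 0 # no naturally occurring folic acid; fortificant only
  sc <- composition_scale()
  for (nm in names(sc)) tb[[nm]] <- tb[[nm]] * sc[[nm]]
  tb
}

# Global density multipliers applied to the base composition values so that
# the national per-AFE intake distributions of the default synthetic survey
# sit at the published operating point (e.g. vitamin A inadequacy ~92%
# without fortification). Part of the generator's fixed study conditions.
composition_scale <- function() {
  c(iron_mg = 1.14, zinc_mg = 0.92, vita_rae_mcg = 0.88, retinol_mcg = 0.88,
    folate_mcg_dfe = 0.89, vitb12_mcg = 1.55)
}

# Component entries behind the two concatenated items, with consumption
# frequency weights in the style of a household budget survey: used to form
# the weighted-mean composition of the composite rows.
composite_components_table <- function() {
  out <- tibble::tribble(
    ~composite_code, ~component, ~hbs_weight, ~energy_kcal, ~iron_mg, ~zinc_mg, ~vita_rae_mcg, ~retinol_mcg, ~folate_mcg_dfe, ~folic_acid_mcg, ~vitb12_mcg, ~source_fct,
    501L, "Onions", 0.38, 40, 0.2, 0.2, 0, 0, 19, 0, 0, "KE18",
    501L, "Tomatoes", 0.45, 18, 0.3, 0.2, 42, 0, 15, 0, 0, "KE18",
    501L, "Carrots", 0.05, 41, 0.3, 0.2, 835, 0, 19, 0, 0, "KE18",
    501L, "Green peppers", 0.12, 20, 0.3, 0.1, 18, 0, 10, 0, 0, "KE18",
    603L, "Mangoes", 0.50, 60, 0.2, 0.1, 54, 0, 43, 0, 0, "KE18",
    603L, "Avocados", 0.25, 160, 0.6, 0.6, 7, 0, 81, 0, 0, "KE18",
    603L, "Other fruits", 0.25, 50, 0.3, 0.1, 10, 0, 15, 0, 0, "WA19"
  )
  sc <- composition_scale()
  for (nm in names(sc)) out[[nm]] <- out[[nm]] * sc[[nm]]
  out
}

# Vehicle mass fractions of processed products. Macaroni/spaghetti carries no
# recipe row by design: its flour cannot be attributed to domestic milling.
default_recipe_table <- function() {
  tibble::tribble(
    ~product_code, ~ingredient, ~mass_fraction,
    "bread", "wheat_flour", 0.62,
    "bread", "cooking_oil", 0.02,
    "buns_cakes_biscuits", "wheat_flour", 0.55,
    "buns_cakes_biscuits", "cooking_oil", 0.15,
    "sweets", "wheat_flour", 0.40,
    "sweets", "cooking_oil", 0.18
  )
}
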