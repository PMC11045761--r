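# ISO 3166-1 alpha-2 country -> reporting macro-region.
#
# Regions follow the continental groupings used in baseline tables of
# spontaneous-report studies: NorthAmerica (incl. Central America and the
# Caribbean), SouthAmerica, Europe, Asia, Oceania, Africa.  Transcontinental
# countries are assigned by their UN M49 macro-region (RU -> Europe,
# TR/CY/GE/AM/AZ/KZ -> Asia, EG -> Africa) so the mapping is deterministic.

COUNTRY_REGION <- c(
  # Northern America
  US = "NorthAmerica", CA = "NorthAmerica", MX = "NorthAmerica",
  GL = "NorthAmerica", BM = "NorthAmerica", PM = "NorthAmerica",
  # Central America & Caribbean
  GT = "NorthAmerica", BZ = "NorthAmerica", SV = "NorthAmerica",
  HN = "NorthAmerica", NI = "NorthAmerica", CR = "NorthAmerica",
  PA = "NorthAmerica", CU = "NorthAmerica", DO = "NorthAmerica",
  HT = "NorthAmerica", JM = "NorthAmerica", TT = "NorthAmerica",
  BS = "NorthAmerica", BB = "NorthAmerica", PR = "NorthAmerica",
  AG = "NorthAmerica", DM = "NorthAmerica", GD = "NorthAmerica",
  KN = "NorthAmerica", LC = "NorthAmerica", VC = "NorthAmerica",
  AW = "NorthAmerica", CW = "NorthAmerica", KY = "NorthAmerica",
  GP = "NorthAmerica", MQ = "NorthAmerica", VG = "NorthAmerica",
  VI = "NorthAmerica",
  # South America
  BR = "SouthAmerica", AR = "SouthAmerica", CL = "SouthAmerica",
  CO = "SouthAmerica", PE = "SouthAmerica", VE = "SouthAmerica",
  EC = "SouthAmerica", BO = "SouthAmerica", PY = "SouthAmerica",
  UY = "SouthAmerica", GY = "SouthAmerica", SR = "SouthAmerica",
  GF = "SouthAmerica", FK = "SouthAmerica",
  # Europe
  GB = "Europe", DE = "Europe", FR = "Europe", IT = "Europe", ES = "Europe",
  PT = "Europe", NL = "Europe", BE = "Europe", LU = "Europe", IE = "Europe",
  DK = "Europe", SE = "Europe", NO = "Europe", FI = "Europe", IS = "Europe",
  CH = "Europe", AT = "Europe", PL = "Europe", CZ = "Europe", SK = "Europe",
  HU = "Europe", RO = "Europe", BG = "Europe", GR = "Europe", HR = "Europe",
  SI = "Europe", RS = "Europe", BA = "Europe", ME = "Europe", MK = "Europe",
  AL = "Europe", EE = "Europe", LV = "Europe", LT = "Europe", BY = "Europe",
  UA = "Europe", MD = "Europe", RU = "Europe", MT = "Europe", LI = "Europe", MC = "Europe", SM = "Europe", VA = "Europe", AD = "Europe",
  GI = "Europe", FO = "Europe", JE = "Europe", GG = "Europe", IM = "Europe",
  XK = "Europe",
  # Asia (incl. Middle East; transcontinental by M49)
  JP = "Asia", CN = "Asia", KR = "Asia", KP = "Asia", TW = "Asia",
  HK = "Asia", MO = "Asia", IN = "Asia", PK = "Asia", BD = "Asia",
  LK = "Asia", NP = "Asia", BT = "Asia", MV = "Asia", MM = "Asia",
  TH = "Asia", VN = "Asia", LA = "Asia", KH = "Asia", MY = "Asia",
  SG = "Asia", ID = "Asia", PH = "Asia", BN = "Asia", TL = "Asia",
  MN = "Asia", KZ = "Asia", KG = "Asia", TJ = "Asia", TM = "Asia",
  UZ = "Asia", AF = "Asia", IR = "Asia", IQ = "Asia", SY = "Asia",
  LB = "Asia", JO = "Asia", IL = "Asia", PS = "Asia", SA = "Asia",
  AE = "Asia", QA = "Asia", BH = "Asia", KW = "Asia", OM = "Asia",
  YE = "Asia", TR = "Asia", CY = "Asia", GE = "Asia", AM = "Asia",
  AZ = "Asia",
  # Oceania
  AU = "Oceania", NZ = "Oceania", FJ = "Oceania", PG = "Oceania",
  SB = "Oceania", VU = "Oceania", NC = "Oceania", PF = "Oceania",
  WS = "Oceania", TO = "Oceania", TV = "Oceania", KI = "Oceania",
  FM = "Oceania", MH = "Oceania", NR = "Oceania", PW = "Oceania",
  GU = "Oceania", CK = "Oceania",
  # Africa
  ZA = "Africa", EG = "Africa", NG = "Africa", KE = "Africa", ET = "Africa",
  GH = "Africa", TZ = "Africa", UG = "Africa", DZ = "Africa", MA = "Africa",
  TN = "Africa", LY = "Africa", SD = "Africa", SS = "Africa", SN = "Africa",
  CI = "Africa", CM = "Africa", CD = "Africa", CG = "Africa", GA = "Africa",
  AO = "Africa", ZM = "Africa", ZW = "Africa", MW = "Africa", MZ = "Africa",
  BW = "Africa", NA_ = "Africa", SZ = "Africa", LS = "Africa", MG = "Africa",
  MU = "Africa", SC = "Africa", RE = "Africa", RW = "Africa", BI = "Africa",
  SO = "Africa", DJ = "Africa", ER = "Africa", ML = "Africa", BF = "Africa",
  NE = "Africa", TD = "Africa", MR = "Africa", GM = "Africa", GN = "Africa",
  GW = "Africa", SL = "Africa", LR = "Africa", TG = "Africa", BJ = "Africa",
  CV = "Africa", ST = "Africa", GQ = "Africa", CF = "Africa", KM = "Africa"
)

REGION_LEVELS <- c("NorthAmerica", "Asia", "Europe", "SouthAmerica",
                   "Oceania", "Africa", "UNK")

#' Map reporter country codes to macro-regions
#'
#' Deterministic total lookup from ISO 3166-1 alpha-2 codes to the six
#' reporting macro-regions used in baseline tables (NorthAmerica, Asia,
#' Europe, SouthAmerica, Oceania, Africa).  Any code not in the shipped
#' table, including missing or empty values, maps to `"UNK"`.
#'
#' @param country_code character vector of country codes (case-insensitive).
#' @return character vector of region codes, same length as the input.
#' @examples
#' map_country_to_region(c("US", "JP", "", "XX"))
#' @export
map_country_to_region <- function(country_code) {
  x <- toupper(trimws(as.character(country_code)))
  # "NA" (Namibia) clashes with R's missing marker in the lookup name
  x[!is.na(x) & x == "NA"] <- "NA_"
  out <- unname(COUNTRY_REGION[x])
  out[is.na(out)] <- "UNK"
  out
}
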