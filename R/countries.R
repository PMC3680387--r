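# Country roster backing the synthetic study tables: ISO3 code, name, WHO
# region, sub-Saharan-Africa advocacy grouping, an approximate 2009 population
# (millions), and the role each country plays in the synthetic panel
# ("included" in the prevalence index, "excluded" by the development-index
# rule, or "daly_only" = burden table only). Populations are round figures for
# a plausible world, not authoritative statistics.

.hh_roster_txt <- "
DZA|Algeria|AFR|0|35.4|included
AGO|Angola|AFR|1|18.5|included
BEN|Benin|AFR|1|8.9|included
BWA|Botswana|AFR|1|2.0|included
BFA|Burkina Faso|AFR|1|15.8|included
BDI|Burundi|AFR|1|8.3|included
CMR|Cameroon|AFR|1|19.5|included
CPV|Cape Verde|AFR|1|0.5|included
CAF|Central African Republic|AFR|1|4.4|included
TCD|Chad|AFR|1|11.2|included
COM|Comoros|AFR|1|0.7|included
COG|Congo|AFR|1|3.9|included
CIV|Cote d'Ivoire|AFR|1|19.7|included
COD|Democratic Republic of the Congo|AFR|1|64.2|included
GNQ|Equatorial Guinea|AFR|1|0.7|included
ERI|Eritrea|AFR|1|5.1|included
ETH|Ethiopia|AFR|1|82.8|included
GAB|Gabon|AFR|1|1.5|included
GMB|Gambia|AFR|1|1.7|included
GHA|Ghana|AFR|1|23.8|included
GIN|Guinea|AFR|1|10.1|included
GNB|Guinea-Bissau|AFR|1|1.5|included
KEN|Kenya|AFR|1|39.5|included
LSO|Lesotho|AFR|1|2.1|included
LBR|Liberia|AFR|1|3.9|included
MDG|Madagascar|AFR|1|19.6|included
MWI|Malawi|AFR|1|14.3|included
MLI|Mali|AFR|1|14.5|included
MRT|Mauritania|AFR|1|3.3|included
MUS|Mauritius|AFR|1|1.3|included
MOZ|Mozambique|AFR|1|22.9|included
NAM|Namibia|AFR|1|2.2|included
NER|Niger|AFR|1|15.3|included
NGA|Nigeria|AFR|1|154.7|included
RWA|Rwanda|AFR|1|10.0|included
STP|Sao Tome and Principe|AFR|1|0.2|included
SEN|Senegal|AFR|1|12.2|included
SYC|Seychelles|AFR|1|0.1|included
SLE|Sierra Leone|AFR|1|5.7|included
ZAF|South Africa|AFR|1|49.3|included
SWZ|Swaziland|AFR|1|1.2|included
TGO|Togo|AFR|1|5.9|included
UGA|Uganda|AFR|1|32.4|included
TZA|United Republic of Tanzania|AFR|1|43.7|included
ZMB|Zambia|AFR|1|12.9|included
ZWE|Zimbabwe|AFR|1|12.5|included
AFG|Afghanistan|EMR|0|28.4|included
DJI|Djibouti|EMR|1|0.9|included
EGY|Egypt|EMR|0|76.8|included
IRN|Iran|EMR|0|72.9|included
IRQ|Iraq|EMR|0|30.7|included
JOR|Jordan|EMR|0|6.3|included
LBN|Lebanon|EMR|0|4.2|included
LBY|Libya|EMR|0|6.4|included
MAR|Morocco|EMR|0|31.9|included
OMN|Oman|EMR|0|2.8|included
PAK|Pakistan|EMR|0|170.5|included
SAU|Saudi Arabia|EMR|0|26.2|included
SDN|Sudan|EMR|1|42.3|included
SYR|Syrian Arab Republic|EMR|0|21.1|included
TUN|Tunisia|EMR|0|10.4|included
YEM|Yemen|EMR|0|23.6|included
BGD|Bangladesh|SEAR|0|147.0|included
BTN|Bhutan|SEAR|0|0.7|included
PRK|Democratic People's Republic of Korea|SEAR|0|24.0|included
IND|India|SEAR|0|1198.0|included
IDN|Indonesia|SEAR|0|237.4|included
MDV|Maldives|SEAR|0|0.3|included
MMR|Myanmar|SEAR|0|50.0|included
NPL|Nepal|SEAR|0|29.3|included
LKA|Sri Lanka|SEAR|0|20.5|included
THA|Thailand|SEAR|0|67.8|included
TLS|Timor-Leste|SEAR|0|1.1|included
ALB|Albania|EUR|0|3.2|included
ARM|Armenia|EUR|0|3.1|included
AZE|Azerbaijan|EUR|0|8.8|included
BLR|Belarus|EUR|0|9.6|included
BIH|Bosnia and Herzegovina|EUR|0|3.8|included
BGR|Bulgaria|EUR|0|7.5|included
HRV|Croatia|EUR|0|4.4|included
EST|Estonia|EUR|0|1.3|included
GEO|Georgia|EUR|0|4.3|included
HUN|Hungary|EUR|0|10.0|included
KAZ|Kazakhstan|EUR|0|15.6|included
KGZ|Kyrgyzstan|EUR|0|5.4|included
LVA|Latvia|EUR|0|2.2|included
LTU|Lithuania|EUR|0|3.3|included
MKD|North Macedonia|EUR|0|2.1|included
MDA|Republic of Moldova|EUR|0|3.6|included
MNE|Montenegro|EUR|0|0.6|included
ROU|Romania|EUR|0|21.5|included
RUS|Russian Federation|EUR|0|141.9|included
SRB|Serbia|EUR|0|7.3|included
TJK|Tajikistan|EUR|0|7.0|included
TUR|Turkey|EUR|0|72.1|included
TKM|Turkmenistan|EUR|0|5.1|included
UKR|Ukraine|EUR|0|46.0|included
UZB|Uzbekistan|EUR|0|27.8|included
ATG|Antigua and Barbuda|AMR|0|0.09|included
ARG|Argentina|AMR|0|40.3|included
BLZ|Belize|AMR|0|0.33|included
BOL|Bolivia|AMR|0|9.9|included
BRA|Brazil|AMR|0|193.7|included
CHL|Chile|AMR|0|17.0|included
COL|Colombia|AMR|0|45.7|included
CRI|Costa Rica|AMR|0|4.6|included
CUB|Cuba|AMR|0|11.2|included
DMA|Dominica|AMR|0|0.07|included
DOM|Dominican Republic|AMR|0|10.1|included
ECU|Ecuador|AMR|0|14.5|included
SLV|El Salvador|AMR|0|6.2|included
GRD|Grenada|AMR|0|0.10|included
GTM|Guatemala|AMR|0|14.0|included
GUY|Guyana|AMR|0|0.76|included
HTI|Haiti|AMR|0|10.0|included
HND|Honduras|AMR|0|7.5|included
JAM|Jamaica|AMR|0|2.7|included
MEX|Mexico|AMR|0|112.0|included
NIC|Nicaragua|AMR|0|5.7|included
PAN|Panama|AMR|0|3.5|included
PRY|Paraguay|AMR|0|6.3|included
PER|Peru|AMR|0|29.2|included
KNA|Saint Kitts and Nevis|AMR|0|0.05|included
LCA|Saint Lucia|AMR|0|0.17|included
VCT|Saint Vincent and the Grenadines|AMR|0|0.11|included
SUR|Suriname|AMR|0|0.52|included
TTO|Trinidad and Tobago|AMR|0|1.3|included
URY|Uruguay|AMR|0|3.4|included
VEN|Venezuela|AMR|0|28.4|included
KHM|Cambodia|WPR|0|14.1|included
CHN|China|WPR|0|1331.0|included
COK|Cook Islands|WPR|0|0.02|included
FJI|Fiji|WPR|0|0.85|included
KIR|Kiribati|WPR|0|0.10|included
LAO|Lao People's Democratic Republic|WPR|0|6.1|included
MYS|Malaysia|WPR|0|27.9|included
MHL|Marshall Islands|WPR|0|0.05|included
FSM|Micronesia|WPR|0|0.11|included
MNG|Mongolia|WPR|0|2.7|included
NRU|Nauru|WPR|0|0.01|included
PLW|Palau|WPR|0|0.02|included
PNG|Papua New Guinea|WPR|0|6.7|included
PHL|Philippines|WPR|0|92.0|included
WSM|Samoa|WPR|0|0.18|included
SLB|Solomon Islands|WPR|0|0.52|included
TON|Tonga|WPR|0|0.10|included
TUV|Tuvalu|WPR|0|0.01|included
VUT|Vanuatu|WPR|0|0.24|included
VNM|Viet Nam|WPR|0|86.0|included
NOR|Norway|EUR|0|4.8|excluded
ISL|Iceland|EUR|0|0.32|excluded
IRL|Ireland|EUR|0|4.5|excluded
NLD|Netherlands|EUR|0|16.5|excluded
SWE|Sweden|EUR|0|9.3|excluded
FRA|France|EUR|0|64.5|excluded
CHE|Switzerland|EUR|0|7.7|excluded
LUX|Luxembourg|EUR|0|0.49|excluded
FIN|Finland|EUR|0|5.3|excluded
AUT|Austria|EUR|0|8.4|excluded
ESP|Spain|EUR|0|45.9|excluded
DNK|Denmark|EUR|0|5.5|excluded
BEL|Belgium|EUR|0|10.8|excluded
ITA|Italy|EUR|0|60.0|excluded
LIE|Liechtenstein|EUR|0|0.04|excluded
GBR|United Kingdom|EUR|0|61.8|excluded
DEU|Germany|EUR|0|81.9|excluded
GRC|Greece|EUR|0|11.2|excluded
AND|Andorra|EUR|0|0.08|excluded
SVN|Slovenia|EUR|0|2.0|excluded
CYP|Cyprus|EUR|0|1.1|excluded
PRT|Portugal|EUR|0|10.6|excluded
CZE|Czechia|EUR|0|10.5|excluded
MLT|Malta|EUR|0|0.41|excluded
MCO|Monaco|EUR|0|0.03|excluded
SMR|San Marino|EUR|0|0.03|excluded
POL|Poland|EUR|0|38.1|excluded
ISR|Israel|EUR|0|7.6|excluded
SVK|Slovakia|EUR|0|5.4|excluded
USA|United States of America|AMR|0|307.0|excluded
CAN|Canada|AMR|0|33.7|excluded
BRB|Barbados|AMR|0|0.28|excluded
JPN|Japan|WPR|0|127.6|excluded
KOR|Republic of Korea|WPR|0|48.7|excluded
AUS|Australia|WPR|0|21.9|excluded
NZL|New Zealand|WPR|0|4.3|excluded
SGP|Singapore|WPR|0|5.0|excluded
BRN|Brunei Darussalam|WPR|0|0.40|excluded
KWT|Kuwait|EMR|0|2.8|excluded
QAT|Qatar|EMR|0|1.6|excluded
ARE|United Arab Emirates|EMR|0|8.2|excluded
BHS|Bahamas|AMR|0|0.34|daly_only
BHR|Bahrain|EMR|0|1.2|daly_only
SOM|Somalia|EMR|1|9.1|daly_only
"

#' Synthetic study country roster
#'
#' Returns the country roster that anchors the synthetic study tables built by
#' [synthetic_appendix()]: ISO3 code, name, WHO region, sub-Saharan-Africa
#' grouping, an approximate 2009 population, and the role of the country in
#' the synthetic panel (`"included"` in the prevalence index, `"excluded"`
#' under the development-index rule, or `"daly_only"` for countries appearing
#' only in the burden table). The roster is synthetic scaffolding: real codes
#' and names, plausible round populations.
#'
#' @return A data.frame with columns `iso3`, `name`, `who_region`,
#'   `ssa_member` (logical), `population_2009` (persons) and `role`.
#' @export
hh_countries <- function() {
  lines <- strsplit(trimws(.hh_roster_txt), "\n", fixed = TRUE)[[1]]
  parts <- strsplit(lines, "|", fixed = TRUE)
  stopifnot(all(lengths(parts) == 6L))
  m <- do.call(rbind, parts)
  out <- data.frame(
    iso3 = m[, 1L],
    name = m[, 2L],
    who_region = m[, 3L],
    ssa_member = m[, 4L] == "1",
    population_2009 = as.numeric(m[, 5L]) * 1e6,
    role = m[, 6L],
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$iso3))
  out
}
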