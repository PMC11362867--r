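# Published bivariate tables for a 56 433-patient Medicare breast-cancer
# surgery cohort (counts by linchpin status of the treating surgeon) and
# the companion 5 631-surgeon table. Columns: non-linchpin, linchpin.
published_patient_tables <- list(
  age = rbind(c(12076, 2115), c(15169, 2835), c(10679, 1973),
              c(5990, 1233), c(3645, 718)),
  race_ethnicity = rbind(c(565, 94), c(2822, 615), c(275, 53), c(141, 34),
                         c(702, 105), c(721, 106), c(42333, 7867)),
  comorbidity = rbind(c(26087, 4482), c(10791, 2078), c(10681, 2314)),
  deprivation = rbind(c(12952, 2073), c(22816, 4234), c(7993, 1674),
                      c(2329, 567), c(1469, 326)),
  nci = rbind(c(41107, 8626), c(6452, 248)),
  rurality = rbind(c(1887, 506), c(2389, 744), c(4738, 1238),
                   c(38545, 6386))
)
published_surgeon_tables <- list(
  gender = rbind(c(1967, 353), c(2779, 532)),
  volume = rbind(c(1450, 309), c(1559, 268), c(1737, 308)),
  rurality = rbind(c(35, 12), c(138, 59), c(605, 165), c(3968, 649)),
  supply = rbind(c(1368, 337), c(1711, 308), c(1667, 240)),
  within_hsa = rbind(c(1509, 368), c(1555, 322), c(1682, 195)),
  between_hsa = rbind(c(1594, 283), c(1573, 304), c(1579, 298))
)
# statistics as printed alongside those tables (1 decimal)
published_chi2 <- c(age = 19.0, comorbidity = 70.3, deprivation = 101.2,
                    nci = 828.3, rurality = 395.1)
published_chi2_surgeon <- c(volume = 6.7, rurality = 62.1, supply = 35.5,
                            within_hsa = 64.6)
# tables reported with p-values only
published_p <- c(gender = 0.41, between_hsa = 0.62)
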