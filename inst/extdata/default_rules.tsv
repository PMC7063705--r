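# psytimex default extraction ruleset
# columns: name <tab> type <tab> priority <tab> hints <tab> pattern
# - patterns are PCRE, matched case-insensitively and wrapped in
#   alphanumeric-boundary lookarounds at load time
# - <MONTH> and <WDAY> expand to month / weekday name alternations
# - hints: ';'-separated key=value pairs, '-' for none; advisory for the
#   normalizer (ref=..., age_mode=..., bounded=1)
# - higher priority wins among equal-length overlapping candidates
name	type	priority	hints	pattern
date_full	DATE	10	-	(?:<WDAY>[ ,]+)?[0-9]{1,2}(?:st|nd|rd|th)?(?: +of)? +<MONTH>,? +[0-9]{4}
date_month_day_year	DATE	10	-	<MONTH> +[0-9]{1,2}(?:st|nd|rd|th)?,? +[0-9]{4}
date_month_year	DATE	5	-	(?:in +)?<MONTH>,? +[0-9]{4}
date_iso	DATE	10	-	[0-9]{4}-[0-9]{2}-[0-9]{2}
date_numeric_ymd	DATE	9	-	[0-9]{4}[/.][0-9]{1,2}[/.][0-9]{1,2}
date_numeric	DATE	8	-	[0-9]{1,2}[/.][0-9]{1,2}[/.][0-9]{2,4}
date_year	DATE	2	-	(?:in +)?(?:19|20)[0-9]{2}
date_deictic	DATE	6	-	(?:today|yesterday|tomorrow)
date_rel_ago	DATE	8	-	(?:(?:about|around|almost|over|nearly) +)?(?:a|an|one|two|three|four|five|six|seven|eight|nine|ten|[0-9]+) +(?:years?|yrs?|months?|weeks?|days?) +(?:ago|back|earlier)
date_last_next	DATE	6	-	(?:last|next) +(?:year|month|week|<MONTH>|<WDAY>)
date_past_ref	DATE	5	ref=PAST_REF	(?:in +the +(?:distant +)?past|historically)
date_present_ref	DATE	5	ref=PRESENT_REF	(?:(?:right +)?now|currently|presently|at +(?:this|the) +(?:time|moment)|at +present|these +days)
time_clock	TIME	9	-	(?:at +)?[0-9]{1,2}(?:[:.][0-9]{2})? *(?:am|pm|a\.m\.|p\.m\.)(?: +sharp)?
time_24h	TIME	7	-	(?:at +)?[0-9]{1,2}:[0-9]{2}(?: *(?:hrs|hours))?
time_daypart	TIME	6	-	(?:in +the +(?:early +|late +)?(?:morning|afternoon|evening)|at +night|tonight|overnight|(?:this|that) +(?:morning|afternoon|evening))
dur_since_date	DURATION	12	bounded=1	(?:since|until|till) +(?:(?:early|late|mid) +)?(?:(?:<WDAY>[ ,]+)?[0-9]{1,2}(?:st|nd|rd|th)? +)?(?:<MONTH>,? +)?(?:19|20)[0-9]{2}
dur_since_deictic	DURATION	12	bounded=1	(?:since|until|till) +(?:today|yesterday|last +(?:year|month|week|<MONTH>))
dur_since_rel	DURATION	12	bounded=1	(?:since|until|till) +(?:a|an|one|two|three|four|five|six|seven|eight|nine|ten|[0-9]+) +(?:years?|yrs?|months?|weeks?|days?) +(?:ago|back|earlier)
dur_for_n	DURATION	11	-	for +(?:(?:about|around|almost|over|nearly|at +least) +)?(?:a|an|one|two|three|four|five|six|seven|eight|nine|ten|[0-9]+) +(?:years?|yrs?|months?|weeks?|days?|hours?|hrs?|min(?:ute)?s?|sec(?:ond)?s?)
dur_for_vague	DURATION	10	-	for +(?:(?:many|several|some|a +few|a +couple +of) +)?(?:hours|days|weeks|months|years|ages)
dur_range_years	DURATION	11	-	(?:19|20)[0-9]{2} *[–—-] *(?:19|20)[0-9]{2}
dur_from_to	DURATION	12	-	from +(?:19|20)[0-9]{2} +(?:to|until|till) +(?:19|20)[0-9]{2}
dur_past_n	DURATION	9	-	(?:over +|in +|during +|for +)?the +(?:past|last) +(?:few +|couple +of +|[0-9]+ +)?(?:years?|months?|weeks?|days?)
dur_bare_n	DURATION	3	-	[0-9]+ +(?:years?|yrs?|months?|weeks?|days?|hours?|min(?:ute)?s?)(?! +(?:old|ago|back|earlier))
freq_adverb	FREQUENCY	6	-	(?:daily|weekly|monthly|nightly|fortnightly|hourly|yearly|annually)
freq_times	FREQUENCY	10	-	(?:once|twice|thrice|three +times|four +times|five +times|[0-9]+ +times) +(?:a|per|every) +(?:day|night|week|month|year|hour)
freq_every	FREQUENCY	8	-	every +(?:other +)?(?:day|night|morning|evening|week|month|year)
age_current	AGE_RELATED	11	age_mode=CURRENT	(?:an? +)?[0-9]{1,3}[- ]+(?:year|yr)s?[- ]+old
age_aged	AGE_RELATED	10	age_mode=CURRENT	aged +[0-9]{1,3}
age_when_n	AGE_RELATED	12	age_mode=PAST	when +(?:he|she|they) +(?:was|were) +(?:only +|about +|around +)?[0-9]{1,3}(?: +(?:years?|months?) +old)?
age_at_age	AGE_RELATED	11	age_mode=PAST	(?:at +(?:the +)?age +(?:of +)?[0-9]{1,3}(?: +(?:years?|months?))?|at +[0-9]{1,3} +years +of +age)
age_since_age	AGE_RELATED	13	bounded=1;age_mode=PAST	(?:since|until|till) +(?:the +)?age +(?:of +)?[0-9]{1,3}(?: +(?:years?|months?))?
age_when_stage	AGE_RELATED	12	-	when +(?:he|she|they) +(?:was|were) +a +(?:child|kid|toddler|baby|teenager|student|young(?:er)? +(?:child|boy|girl|man|woman))
age_poss_stage	AGE_RELATED	11	-	(?:since|until|in|during|from|throughout) +(?:his|her|their) +(?:early +|late +|mid[- ]?)?(?:teens|twenties|thirties|childhood|adolescence|school +(?:years|days)|university +(?:years|days)|adult +life|adulthood)
age_bare_stage	AGE_RELATED	9	-	(?:in|during|since|throughout) +(?:childhood|adolescence|primary +school|secondary +school|university|adulthood)
age_as_stage	AGE_RELATED	9	-	as +a +(?:child|kid|teenager|young +(?:man|woman|adult)|boy|girl)
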