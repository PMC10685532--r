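{
  "char_map": {
    "ي": ["ی"],
    "ى": ["ی"],
    "ك": ["ک"],
    "أ": ["ا"],
    "إ": ["ا"],
    "ٱ": ["ا"],
    "ؤ": ["و"],
    "ة": ["ه"],
    "اب": ["آب"],
    "اباد": ["آباد"],
    "ارام": ["آرام"],
    "ارامش": ["آرامش"],
    "اقا": ["آقا"],
    "اینده": ["آینده"]
  },
  "spelling_variants": {
    "اطاق": ["اتاق"],
    "بلیط": ["بلیت"],
    "طهران": ["تهران"],
    "اطو": ["اتو"],
    "پیر مرد": ["پیرمرد"],
    "شیمی درمانی": ["شیمی‌درمانی"]
  },
  "suffixes": ["ترین", "تر", "هایم", "هایش", "هایت", "هایی", "های", "ها"],
  "prefixes": ["نمی", "درمی", "برمی", "می", "بی"],
  "stopwords": ["از", "به", "با", "در", "که", "را", "و", "این", "آن", "است", "هست", "بود", "شد", "شده", "برای", "تا", "هم", "یا", "اگر", "هر", "او", "ما", "شما", "آنها", "ایشان", "من", "تو", "خود", "چه", "چون", "زیرا", "ولی", "اما", "نیز", "بر", "روی", "بین", "پیش", "پس", "چند", "یک", "دو", "سه", "آیا", "باید", "شاید", "البته", "یعنی", "فقط", "حتی", "دیگر", "همه", "بعضی", "کسی", "چیزی", "جا", "همین", "همان", "وقتی", "سپس", "کنار", "مثل", "مانند", "طبق", "بدون", "درباره", "اینکه", "آنکه", "بله", "خیر", "اکنون", "حالا", "الان", "دیروز", "امروز", "فردا", "آنجا", "اینجا"],
  "shifters": ["ضد", "نا", "ن"],
  "protected_words": ["نان", "نام", "ناهار", "نامه", "ناراحت", "نگران", "ضدعفونی"],
  "elongation_chars": ["ـ"],
  "punctuation": [".", "،", "؛", "؟", "!", "?", ",", ";", ":", "(", ")", "[", "]", "{", "}", "«", "»", "\"", "'", "…", "۔"]
}
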