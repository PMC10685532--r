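از
به
با
در
که
را
و
این
آن
است
هست
بود
شد
شده
برای
تا
هم
یا
اگر
هر
او
ما
شما
آنها
ایشان
من
تو
خود
چه
چون
زیرا
ولی
اما
نیز
بر
روی
بین
پیش
پس
چند
یک
دو
سه
آیا
باید
شاید
البته
یعنی
فقط
حتی
دیگر
همه
بعضی
کسی
چیزی
جا
همین
همان
وقتی
سپس
کنار
مثل
مانند
طبق
بدون
درباره
اینکه
آنکه
بله
خیر
اکنون
حالا
الان
دیروز
امروز
فردا
آنجا
اینجا
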